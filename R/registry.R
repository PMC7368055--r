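#' The microspot / parameter coding registry
#'
#' The assay design is pinned in a versioned JSON registry shipped with the
#' package: nine microspot surfaces (`M1`--`M9`, from the BSA control through
#' the collagen-related surfaces to the thrombomodulin / activated-protein-C
#' co-coated anticoagulant spots), nine kinetic readouts (`P1`--`P9`: platelet
#' adhesion and phosphatidylserine exposure by percent surface-area coverage,
#' thrombus coverage / morphology / aggregation / contraction, fibrin
#' deposition and score, and the shortened time-to-fibrin statistic), and the
#' three thrombin-generation curve characteristics (`C1`--`C3`). All
#' downstream tables carry ids from this registry so that analyses are
#' reproducible against a pinned coding.
#'
#' @return `assay_registry()` returns the full registry as a nested list with
#'   a `schema_version`; `microspot_registry()` and `parameter_registry()`
#'   return one-row-per-entry tibbles.
#' @examples
#' microspot_registry()
#' parameter_registry()
#' @export
assay_registry <- function() {
  env <- .registry_cache
  if (is.null(env$registry)) {
    path <- system.file("extdata", "registry.json", package = "thrombospot")
    env$registry <- jsonlite::read_json(path)
    .validate_registry(env$registry)
  }
  env$registry
}

.registry_cache <- new.env(parent = emptyenv())

.validate_registry <- function(reg) {
  ms <- reg$microspots
  stopifnot(!anyDuplicated(names(ms)))
  for (m in ms) {
    # TF co-coating and TM/APC co-coating are mutually exclusive by design
    if (identical(m$co_coating, "TF") && isTRUE(m$tf_in_medium)) {
      abort(sprintf("registry entry %s: TF co-coating with TF in medium", m$id))
    }
    conc <- vapply(m$coating, function(x) x$value %||% 0, numeric(1))
    if (any(conc < 0)) abort(sprintf("registry entry %s: negative concentration", m$id))
  }
  invisible(reg)
}

#' @rdname assay_registry
#' @export
microspot_registry <- function() {
  reg <- assay_registry()
  purrr::map(reg$microspots, function(m) {
    tibble(
      surface = m$id,
      label = m$label,
      coating = paste(
        vapply(m$coating, function(x) {
          sprintf("%s %s %s", x$component, format(x$value %||% ""), x$unit %||% "")
        }, character(1)),
        collapse = " + "
      ),
      co_coating = m$co_coating %||% "none",
      receptors = paste(unlist(m$receptors), collapse = ","),
      tf_in_medium = isTRUE(m$tf_in_medium)
    )
  }) |> list_rbind()
}

#' @rdname assay_registry
#' @export
parameter_registry <- function() {
  reg <- assay_registry()
  purrr::map(reg$parameters, function(p) {
    tibble(
      parameter = p$id,
      label = p$label,
      channel = p$channel,
      unit = p$unit,
      range_min = p$range[[1]],
      range_max = p$range[[2]],
      group = p$group
    )
  }) |> list_rbind()
}

#' Look up one registry entry
#'
#' @param id A surface id (`"M1"`--`"M9"`) or parameter id (`"P1"`--`"P9"`).
#' @return The immutable registry entry as a list.
#' @examples
#' registry_lookup("M6")$label
#' registry_lookup("P9")$unit
#' @export
registry_lookup <- function(id) {
  stopifnot(is.character(id), length(id) == 1)
  reg <- assay_registry()
  entry <- reg$microspots[[id]] %||% reg$parameters[[id]] %||%
    reg$curve_characteristics[[id]]
  if (is.null(entry)) {
    abort(sprintf("unknown registry id '%s'", id), class = "thrombospot_not_found")
  }
  entry
}

#' Map an intervention triple to its condition class
#'
#' The eight experimental classes are the combinations of tissue factor (TF),
#' active-site inactivated factor VIIa (iFVIIa) and corn trypsin inhibitor
#' (CTI) being present or absent. The bit order is fixed as TF = 4, iFVIIa =
#' 2, CTI = 1, giving a bijection onto 0..7 that is recorded in all prediction
#' outputs.
#'
#' @param tf,ifviia,cti Logical vectors (recycled to a common length).
#' @return Integer vector of class indices in 0..7.
#' @examples
#' condition_class(FALSE, FALSE, FALSE)  # 0
#' condition_class(TRUE, TRUE, TRUE)     # 7
#' @export
condition_class <- function(tf, ifviia, cti) {
  n <- max(length(tf), length(ifviia), length(cti))
  tf <- rep_len(as.logical(tf), n)
  ifviia <- rep_len(as.logical(ifviia), n)
  cti <- rep_len(as.logical(cti), n)
  if (anyNA(tf) || anyNA(ifviia) || anyNA(cti)) abort("condition flags must be TRUE/FALSE")
  as.integer(tf) * 4L + as.integer(ifviia) * 2L + as.integer(cti)
}

#' Parameter groups used for integration
#'
#' Platelet adhesion/activation (`P1`--`P2`), thrombus signature
#' (`P3`--`P6`) and fibrin formation (`P7`--`P9`): the disjoint grouping used
#' when cumulating patient-versus-control changes.
#'
#' @return Named list of parameter-id character vectors.
#' @export
parameter_groups <- function() {
  list(
    platelet = c("P1", "P2"),
    thrombus = c("P3", "P4", "P5", "P6"),
    fibrin = c("P7", "P8", "P9")
  )
}

#' Validate a long-format parameter record table
#'
#' A complete record per subject x surface x condition holds 41 values: eight
#' parameters at the five capture times (0, 2, 4, 6, 8 min) plus the scalar
#' time-to-fibrin statistic `P9`. Values are checked against the registry
#' ranges; score parameters must be integral.
#'
#' @param records Tibble with at least `parameter`, `time`, `value` columns
#'   (long format; `P9` rows have `time = NA`).
#' @param complete Require exactly 41 values per record unit (default TRUE).
#' @return `records`, invisibly, or an error describing the violation.
#' @export
validate_records <- function(records, complete = TRUE) {
  pr <- parameter_registry()
  chk <- records |>
    left_join(pr, by = "parameter")
  if (anyNA(chk$unit)) {
    abort(sprintf(
      "unknown parameter id(s): %s",
      paste(unique(chk$parameter[is.na(chk$unit)]), collapse = ", ")
    ))
  }
  ok <- is.na(chk$value) |
    (chk$value >= chk$range_min & chk$value <= chk$range_max)
  if (!all(ok)) {
    bad <- chk[!ok, , drop = FALSE]
    abort(sprintf(
      "%d value(s) out of range, e.g. %s = %g outside [%g, %g]",
      sum(!ok), bad$parameter[1], bad$value[1], bad$range_min[1], bad$range_max[1]
    ))
  }
  is_score <- chk$unit == "score" & !is.na(chk$value)
  if (any(is_score & chk$value != round(chk$value))) {
    abort("score parameters must be integer-valued")
  }
  if (complete) {
    keys <- setdiff(
      names(records),
      c("parameter", "time", "value", "provenance", "seed")
    )
    n <- records |>
      summarise(n = n(), .by = all_of(keys))
    if (any(n$n != 41L)) {
      abort(sprintf(
        "incomplete record(s): expected 41 values per record, got %s",
        paste(unique(n$n[n$n != 41L]), collapse = ", ")
      ))
    }
  }
  invisible(records)
}
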