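#' Built-in registry of beta-eliminative linker modulators
#'
#' Reference release half-lives for the arylsulfonyl/alkylsulfonyl modulators
#' used with the microsphere platform, at pH 7.4 and 37 degrees C. These are
#' literature values shipped as a convenience fixture; they can be replaced or
#' extended by editing a YAML/JSON registry file and loading it with
#' [read_linker_registry()]. `t_rg_h` is the time to reverse gelation of the
#' carrying hydrogel (crosslink cleavage dissolving the gel), which must
#' exceed the drug-release half-life so the depot outlives payload release;
#' it is `NA` where not characterised.
#'
#' @return A tibble with columns `modulator_name`, `t_half_ref_h`, `ph_ref`,
#'   `temp_ref_c`, `t_rg_h`.
#' @examples
#' linker_registry()
#' @export
linker_registry <- function() {
  tibble::tibble(
    modulator_name = c("4-ClPhSO2", "PhSO2", "4-MePhSO2", "MeSO2"),
    t_half_ref_h = c(9, 27, 40, 160),
    ph_ref = 7.4,
    temp_ref_c = 37,
    t_rg_h = c(1000, 1000, 1000, NA_real_)
  )
}

registry_columns <- c("modulator_name", "t_half_ref_h", "ph_ref", "temp_ref_c")

validate_registry <- function(reg) {
  missing <- setdiff(registry_columns, names(reg))
  if (length(missing) > 0) {
    abort(sprintf(
      "Linker registry is missing column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"t_rg_h" %in% names(reg)) reg$t_rg_h <- NA_real_
  reg <- tibble::as_tibble(reg)[, c(registry_columns, "t_rg_h")]
  check_positive(reg$t_half_ref_h, "t_half_ref_h")
  check_ph(reg$ph_ref, "ph_ref")
  bad_rg <- !is.na(reg$t_rg_h) & reg$t_rg_h <= reg$t_half_ref_h
  if (any(bad_rg)) {
    abort(sprintf(
      "t_rg_h must exceed t_half_ref_h (gel must outlive drug release); offending modulator(s): %s.",
      paste(reg$modulator_name[bad_rg], collapse = ", ")
    ))
  }
  reg
}

#' Read or write a linker registry file
#'
#' The registry is a YAML (or JSON) list of records with fields
#' `modulator_name`, `t_half_ref_h`, `ph_ref`, `temp_ref_c` and optional
#' `t_rg_h`. Records are validated on load: positive half-lives, pH within
#' (0, 14), and any reverse-gelation time strictly greater than the release
#' half-life.
#'
#' @param path File path. YAML is the native format; `.json` files are also
#'   accepted on read (YAML is a superset of JSON).
#' @param registry A data frame with the registry columns, e.g. from
#'   [linker_registry()].
#' @return `read_linker_registry()` returns a validated tibble;
#'   `write_linker_registry()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_linker_registry(linker_registry(), path)
#' read_linker_registry(path)
#' @export
read_linker_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("Registry file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$linkers)) raw <- raw$linkers
  reg <- dplyr::bind_rows(lapply(raw, function(rec) {
    tibble::as_tibble(rec[!vapply(rec, is.null, logical(1))])
  }))
  validate_registry(reg)
}

#' @rdname read_linker_registry
#' @export
write_linker_registry <- function(registry, path) {
  reg <- validate_registry(registry)
  recs <- lapply(seq_len(nrow(reg)), function(i) {
    rec <- as.list(reg[i, ])
    if (is.na(rec$t_rg_h)) rec$t_rg_h <- NULL
    rec
  })
  yaml::write_yaml(list(linkers = recs), path)
  invisible(path)
}
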