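# Sparse 13C labeling schemes.  Growth on 2-13C- or 1,6-13C-glucose places
# 13C at biosynthesis-determined positions, thinning spectral overlap; which
# atom pairs can produce an observable CC or NC correlation depends on the
# per-site label fraction.  Patterns are DATA (editable TSV tables with
# literature-derived defaults), not code.

#' Construct a labeling scheme
#'
#' @param name scheme name.
#' @param table data frame with columns `restype`, `atom`, `fraction`
#'   (label fraction in 0-1).  `"*"` wildcards are allowed in `restype`
#'   and/or `atom`; the most specific match wins.
#' @param nitrogen_labeled is 15N uniformly labeled?
#' @param threshold minimum label fraction for a site to count as observable.
#' @param strict error (rather than return 0) when a queried (restype, atom)
#'   resolves to no table row.
#' @return an object of class `labeling_scheme`.
#' @export
labeling_scheme <- function(name, table, nitrogen_labeled = TRUE,
                            threshold = 0.1, strict = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("restype", "atom", "fraction") %in% names(table)))
  if (any(!is.finite(table$fraction) | table$fraction < 0 | table$fraction > 1))
    stop("label fractions must lie in [0, 1]")
  structure(list(name = name, table = table,
                 nitrogen_labeled = isTRUE(nitrogen_labeled),
                 threshold = threshold, strict = isTRUE(strict)),
            class = "labeling_scheme")
}

#' @export
print.labeling_scheme <- function(x, ...) {
  cat(sprintf("labeling_scheme '%s': %d rows, 15N %slabeled, threshold %.2f\n",
              x$name, nrow(x$table), if (x$nitrogen_labeled) "" else "un",
              x$threshold))
  invisible(x)
}

#' Load a labeling scheme
#'
#' Accepts either a built-in name — `"U-13C6"` (every carbon fraction 1.0),
#' `"2-13C-glucose"`, `"1,6-13C-glucose"` (packaged literature-derived
#' tables, user-overridable) — or a path to a TSV file with columns
#' `restype`, `atom`, `fraction`.
#'
#' @param config scheme name or TSV path.
#' @param nitrogen_labeled is 15N uniformly labeled (default TRUE).
#' @param threshold observability threshold (default 0.1).
#' @param strict strict lookup mode (see [labeling_scheme()]).
#' @return a `labeling_scheme`.
#' @export
load_scheme <- function(config, nitrogen_labeled = TRUE, threshold = 0.1,
                        strict = FALSE) {
  builtin <- c("U-13C6" = "labeling_u13c6.tsv",
               "2-13C-glucose" = "labeling_2_13C_glucose.tsv",
               "1,6-13C-glucose" = "labeling_1_6_13C_glucose.tsv")
  path <- config
  name <- config
  if (config %in% names(builtin)) {
    path <- system.file("extdata", builtin[[config]], package = "masnmr")
    if (path == "") path <- file.path("inst", "extdata", builtin[[config]])
  } else if (!file.exists(config)) {
    stop("unknown scheme or missing file: ", config)
  }
  lines <- readLines(path)
  body <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  tab <- tryCatch(
    utils::read.delim(text = lines[body], stringsAsFactors = FALSE),
    error = function(e) stop("malformed labeling table ", path, ": ",
                             conditionMessage(e)))
  need <- c("restype", "atom", "fraction")
  if (!all(need %in% names(tab)))
    stop("labeling table must have columns restype, atom, fraction: ", path)
  frac <- suppressWarnings(as.numeric(tab$fraction))
  bad <- which(!is.finite(frac) | frac < 0 | frac > 1)
  if (length(bad)) {
    ln <- which(body)[bad[1L] + 1L]  # +1 for the header line
    stop("bad fraction at line ", ln, " of ", path)
  }
  tab$fraction <- frac
  labeling_scheme(name, tab, nitrogen_labeled = nitrogen_labeled,
                  threshold = threshold, strict = strict)
}

#' Label fraction of one site
#'
#' Resolution order: exact (restype, atom), then (`"*"`, atom), then
#' (restype, `"*"`), then (`"*"`, `"*"`).
#'
#' @param scheme a `labeling_scheme`.
#' @param restype 3-letter residue type.
#' @param atom atom name.
#' @return fraction in 0-1; 0 if unresolved (error in strict mode).
#' @export
label_fraction <- function(scheme, restype, atom) {
  t <- scheme$table
  for (k in list(c(restype, atom), c("*", atom), c(restype, "*"), c("*", "*"))) {
    hit <- which(t$restype == k[1L] & t$atom == k[2L])
    if (length(hit)) return(t$fraction[hit[1L]])
  }
  if (scheme$strict)
    stop("labeling scheme '", scheme$name, "' has no entry for (",
         restype, ", ", atom, ")")
  0
}

#' Can an atom pair produce an observable correlation?
#'
#' CC correlations require both carbons labeled above the scheme threshold;
#' NC correlations require uniform 15N labeling plus a labeled carbon.
#'
#' @param scheme a `labeling_scheme`.
#' @param a,b atom descriptors: list/vector with `restype`, `atom` (and
#'   optionally `element`, inferred from the name otherwise).
#' @param experiment `"CC"` or `"NC"`.
#' @return logical.
#' @export
pair_observable <- function(scheme, a, b, experiment = c("CC", "NC")) {
  experiment <- match.arg(experiment)
  getel <- function(x) (x[["element"]] %||% infer_element(x[["atom"]]))
  ea <- getel(a); eb <- getel(b)
  frac <- function(x) label_fraction(scheme, x[["restype"]], x[["atom"]])
  thr <- scheme$threshold
  if (experiment == "CC") {
    if (ea != "C" || eb != "C") return(FALSE)
    return(frac(a) >= thr && frac(b) >= thr)
  }
  # NC: exactly one nitrogen site and one carbon site
  if (ea == "N" && eb == "C") return(scheme$nitrogen_labeled && frac(b) >= thr)
  if (ea == "C" && eb == "N") return(scheme$nitrogen_labeled && frac(a) >= thr)
  FALSE
}
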