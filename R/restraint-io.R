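# Restraint file I/O: native TSV (lossless round-trip), XPLOR/CNS NOE
# "assign" tables (write + read), a minimal NMR-STAR v3 restraint-loop
# reader, and a TALOS-style torsion prediction table reader.

#' Read / write restraint sets as native TSV
#'
#' The native dialect is the `restraint_set` data frame itself; write
#' followed by read is the identity.
#'
#' @param rset a `restraint_set`.
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader a
#'   [restraint_set()].
#' @export
write_restraints_tsv <- function(rset, path) {
  utils::write.table(as.data.frame(rset), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_restraints_tsv
#' @export
read_restraints_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  restraint_set(df)
}

#' Write an XPLOR/CNS NOE assign table
#'
#' One `assign` statement per restraint,
#' `assign (resid i and name X)(resid j and name Y) d dminus dplus`
#' with `d - dminus = lower` and `d + dplus = upper` (d is the midpoint).
#' Ambiguous groups are emitted as OR-ed selections in the second selector.
#'
#' @param rset a `restraint_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_xplor <- function(rset, path) {
  lines <- character(0)
  for (id in unique(rset$restraint_id)) {
    g <- rset[rset$restraint_id == id, , drop = FALSE]
    lo <- g$lower[1L]; up <- g$upper[1L]
    d <- (lo + up) / 2
    sel1 <- sprintf("(resid %d and name %s)", g$res_a[1L], g$atom_a[1L])
    sel2 <- paste(sprintf("(resid %d and name %s)", g$res_b, g$atom_b),
                  collapse = " or ")
    if (nrow(g) > 1L) sel2 <- paste0("(", sel2, ")")
    lines <- c(lines, sprintf("assign %s%s %.2f %.2f %.2f",
                              sel1, sel2, d, d - lo, up - d))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an XPLOR/CNS NOE assign table
#'
#' Parses the dialect emitted by [write_xplor()]: simple
#' `(resid i and name X)` selectors, with OR-groups in the second selector
#' treated as ambiguous restraint members.
#'
#' @param path file path.
#' @return a [restraint_set()].
#' @export
read_xplor <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  rows <- list(); rid <- 0L
  for (ln_no in seq_along(lines)) {
    ln <- lines[ln_no]
    if (!grepl("^assign", ln, ignore.case = TRUE)) next
    sels <- regmatches(ln, gregexpr("resid\\s+(-?[0-9]+)\\s+and\\s+name\\s+(\\S+?)\\)",
                                    ln, perl = TRUE))[[1L]]
    nums <- regmatches(ln, gregexpr("-?[0-9.]+\\s*$|\\s-?[0-9.]+", ln))
    tail_nums <- utils::tail(strsplit(ln, "\\)")[[1L]], 1L)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(tail_nums), "\\s+")[[1L]]))
    vals <- vals[is.finite(vals)]
    if (length(sels) < 2L || length(vals) < 3L)
      stop("XPLOR parse failure at line ", ln_no, ": ", ln)
    parse_sel <- function(s) {
      m <- regmatches(s, regexec("resid\\s+(-?[0-9]+)\\s+and\\s+name\\s+(\\S+?)\\)", s))[[1L]]
      list(resid = as.integer(m[2L]), atom = m[3L])
    }
    first <- parse_sel(sels[1L])
    partners <- lapply(sels[-1L], parse_sel)
    d <- vals[1L]; dminus <- vals[2L]; dplus <- vals[3L]
    rid <- rid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      restraint_id = rid, member = seq_along(partners),
      res_a = first$resid, atom_a = first$atom,
      res_b = vapply(partners, `[[`, integer(1L), "resid"),
      atom_b = vapply(partners, `[[`, character(1L), "atom"),
      lower = d - dminus, upper = d + dplus,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(restraint_set())
  restraint_set(do.call(rbind, rows))
}

#' Minimal NMR-STAR v3 restraint reader
#'
#' Extracts distance restraints from `_Gen_dist_constraint` loops and
#' torsion restraints from `_Torsion_angle_constraint` loops.  Tolerant of
#' both OR-group listings (shared constraint ID, multiple member rows) and
#' per-pair listings.
#'
#' @param path NMR-STAR file path.
#' @return list with `distance` (a [restraint_set()]) and `torsion` (a
#'   [torsion_restraints()] or NULL).
#' @export
read_nmrstar_restraints <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  parse_loop <- function(prefix) {
    starts <- which(lines == "loop_")
    for (s in starts) {
      tags <- character(0); i <- s + 1L
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        tags <- c(tags, lines[i]); i <- i + 1L
      }
      if (!length(tags) || !all(startsWith(tags, paste0("_", prefix, ".")))) next
      body <- character(0)
      while (i <= length(lines) && lines[i] != "stop_" && lines[i] != "") {
        if (nzchar(lines[i]) && !startsWith(lines[i], "#"))
          body <- c(body, lines[i])
        i <- i + 1L
      }
      if (!length(body)) return(NULL)
      fields <- lapply(body, function(b) strsplit(b, "\\s+")[[1L]])
      nf <- lengths(fields)
      if (any(nf != length(tags)))
        stop("NMR-STAR parse failure in loop ", prefix,
             ": row has wrong field count")
      m <- do.call(rbind, fields)
      colnames(m) <- sub(paste0("^_", prefix, "\\."), "", tags)
      return(as.data.frame(m, stringsAsFactors = FALSE))
    }
    NULL
  }
  dist_raw <- parse_loop("Gen_dist_constraint")
  dist <- restraint_set()
  if (!is.null(dist_raw)) {
    getcol <- function(df, ...) {
      for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
      stop("NMR-STAR distance loop missing column: ", ..1)
    }
    df <- data.frame(
      restraint_id = as.integer(getcol(dist_raw, "ID", "Constraint_ID")),
      res_a = as.integer(getcol(dist_raw, "Comp_index_ID_1", "Seq_ID_1")),
      atom_a = getcol(dist_raw, "Atom_ID_1"),
      res_b = as.integer(getcol(dist_raw, "Comp_index_ID_2", "Seq_ID_2")),
      atom_b = getcol(dist_raw, "Atom_ID_2"),
      lower = as.numeric(getcol(dist_raw, "Distance_lower_bound_val",
                                "Lower_bound")),
      upper = as.numeric(getcol(dist_raw, "Distance_upper_bound_val",
                                "Upper_bound")),
      stringsAsFactors = FALSE)
    dist <- restraint_set(df)
  }
  tor_raw <- parse_loop("Torsion_angle_constraint")
  tor <- NULL
  if (!is.null(tor_raw)) {
    lo <- as.numeric(tor_raw$Angle_lower_bound_val)
    up <- as.numeric(tor_raw$Angle_upper_bound_val)
    tor <- torsion_restraints(data.frame(
      resid = as.integer(tor_raw$Comp_index_ID_2 %||% tor_raw$Seq_ID_2),
      angle = tolower(tor_raw$Torsion_angle_name),
      center = wrap_angle((lo + up) / 2),
      halfwidth = (up - lo) / 2,
      stringsAsFactors = FALSE))
  }
  list(distance = dist, torsion = tor)
}

#' Read a TALOS-style torsion prediction table
#'
#' Parses the `VARS`/`FORMAT` tabular dialect of backbone dihedral
#' predictions and converts predicted phi/psi with their uncertainty columns
#' into [torsion_restraints()].  Rows with a non-"Good" classification (when
#' a CLASS column is present) are skipped.
#'
#' @param path prediction table path.
#' @param fallback_halfwidth half-width when the uncertainty column is
#'   missing or zero (degrees, default 20).
#' @return a [torsion_restraints()].
#' @export
read_talos <- function(path, fallback_halfwidth = 20) {
  lines <- readLines(path)
  vars_ln <- grep("^VARS\\b", lines, value = TRUE)
  if (!length(vars_ln)) stop("not a TALOS-style table (no VARS line): ", path)
  vars <- strsplit(trimws(sub("^VARS", "", vars_ln[1L])), "\\s+")[[1L]]
  body <- lines[!grepl("^(VARS|FORMAT|REMARK|DATA|#)", lines) & nzchar(trimws(lines))]
  if (!length(body)) return(torsion_restraints(
    data.frame(resid = integer(0), angle = character(0),
               center = numeric(0), halfwidth = numeric(0))))
  m <- do.call(rbind, lapply(body, function(b) strsplit(trimws(b), "\\s+")[[1L]]))
  colnames(m) <- vars
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  if ("CLASS" %in% names(df)) df <- df[df$CLASS %in% c("Good", "Strong"), , drop = FALSE]
  num <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else NULL
  resid <- as.integer(df$RESID)
  out <- list()
  for (ang in c("PHI", "PSI")) {
    center <- num(ang)
    if (is.null(center)) next
    hw <- num(paste0("D", ang))
    if (is.null(hw)) hw <- rep(fallback_halfwidth, length(center))
    hw[!is.finite(hw) | hw <= 0] <- fallback_halfwidth
    out[[ang]] <- data.frame(resid = resid, angle = tolower(ang),
                             center = wrap_angle(center), halfwidth = hw,
                             stringsAsFactors = FALSE)
  }
  torsion_restraints(do.call(rbind, out))
}
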