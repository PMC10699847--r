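# Readers and writers for the external formats the toolkit touches. PDB and
# aligned-FASTA parsing is delegated to bio3d; the distogram, mode-matrix,
# metric-CSV and secondary-structure formats are package-defined text
# formats.

#' Parse report accompanying a reader
#'
#' @param warnings data.frame with columns severity, ref, message.
#' @param n_records number of records retained.
#' @return an object of class `parse_report`.
#' @export
parse_report <- function(warnings = NULL, n_records = 0L) {
  if (is.null(warnings))
    warnings <- data.frame(severity = character(), ref = character(),
                           message = character())
  structure(list(warnings = warnings, n_records = as.integer(n_records)),
            class = "parse_report")
}

#' @export
print.parse_report <- function(x, ...) {
  cat(sprintf("parse_report: %d records, %d warnings\n",
              x$n_records, nrow(x$warnings)))
  if (nrow(x$warnings))
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  [%s] %s: %s\n", x$warnings$severity[i],
                  x$warnings$ref[i], x$warnings$message[i]))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Reads the first model of a PDB file (via bio3d), resolves alternate
#' locations to the highest occupancy (ties to the lowest altloc letter),
#' skips HETATM records except nonstandard residues with a standard parent
#' mapping (MSE -> MET, with SE renamed to SD), and preserves author residue
#' numbering. Every skipped or remapped record leaves a warning in the parse
#' report.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; default: the first chain in the
#'   file.
#' @return list with `structure` (a `structure_model`) and `report` (a
#'   [parse_report()]).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop_format("cannot parse PDB %s: %s",
                                                  path, conditionMessage(e)))
  at <- pdb$atom
  warn <- list()
  note <- function(sev, ref, msg)
    warn[[length(warn) + 1L]] <<- data.frame(severity = sev, ref = ref,
                                             message = msg)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop_format("chain '%s' absent from %s", chain, path)

  # HETATM records: keep only residues with a standard parent mapping
  het <- at$type == "HETATM"
  mapped <- at$resid %in% names(NONSTANDARD_PARENT)
  if (any(het & !mapped)) {
    for (rid in unique(at$resid[het & !mapped]))
      note("info", rid, "HETATM residue skipped")
    at <- at[!(het & !mapped), , drop = FALSE]
  }
  if (!nrow(at)) stop_format("no usable ATOM records in chain '%s'", chain)
  for (rid in intersect(unique(at$resid), names(NONSTANDARD_PARENT))) {
    note("warning", rid,
         sprintf("nonstandard residue mapped to %s", NONSTANDARD_PARENT[[rid]]))
    sel <- at$resid == rid
    if (rid == "MSE") at$elety[sel & at$elety == "SE"] <- "SD"
    at$resid[sel] <- NONSTANDARD_PARENT[[rid]]
  }

  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  reskey <- paste(at$resno, ins, sep = "|")
  residues <- list()
  for (key in unique(reskey)) {
    ra <- at[reskey == key, , drop = FALSE]
    # altloc resolution per atom name
    alt <- ifelse(is.na(ra$alt) | ra$alt == "", "", ra$alt)
    if (anyDuplicated(ra$elety)) {
      pick <- integer()
      for (nm in unique(ra$elety)) {
        idx <- which(ra$elety == nm)
        if (length(idx) > 1) {
          occ <- ra$o[idx]; occ[is.na(occ)] <- 1
          best <- idx[order(-occ, alt[idx])][1]
          note("warning", sprintf("%s%s %s", ra$resid[1], ra$resno[1], nm),
               sprintf("altloc resolved to '%s' (occupancy %.2f)",
                       alt[best], occ[order(-occ, alt[idx])][1]))
          pick <- c(pick, best)
        } else pick <- c(pick, idx)
      }
      ra <- ra[sort(pick), , drop = FALSE]
    }
    atoms <- lapply(seq_len(nrow(ra)), function(i)
      c(ra$x[i], ra$y[i], ra$z[i]))
    names(atoms) <- ra$elety
    if (any(!is.finite(unlist(atoms)))) {
      note("warning", key, "non-finite coordinates: residue skipped")
      next
    }
    residues[[length(residues) + 1L]] <-
      residue_model(ra$resid[1], ra$resno[1], atoms)
  }
  if (!length(residues)) stop_format("no residues parsed from %s", path)
  s <- structure_model(residues, chain_id = chain[1])
  for (i in which(s$incomplete))
    note("warning", sprintf("%s%d", residues[[i]]$name, residues[[i]]$index),
         "incomplete backbone (missing N/CA/C)")
  for (i in which(s$nonstandard))
    note("warning", sprintf("%s%d", residues[[i]]$name, residues[[i]]$index),
         "nonstandard residue without parent mapping")
  list(structure = s,
       report = parse_report(do.call(rbind, warn), length(residues)))
}

#' Read a pairwise alignment from aligned FASTA
#'
#' Expects exactly two records of equal aligned length; columns where both
#' rows carry a residue become matched pairs, gap (`-`) columns are skipped.
#'
#' @param path aligned-FASTA file path.
#' @return a [pair_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  aln <- tryCatch(bio3d::read.fasta(path),
                  error = function(e) stop_format("cannot parse FASTA %s: %s",
                                                  path, conditionMessage(e)))
  ali <- aln$ali
  if (nrow(ali) != 2)
    stop_format("alignment must contain exactly 2 records, found %d", nrow(ali))
  a <- toupper(ali[1, ]); b <- toupper(ali[2, ])
  raw <- vapply(seq_len(nrow(ali)), function(i)
    sum(!(toupper(ali[i, ]) %in% c("-", "."))), 0L)
  both <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  qpos <- cumsum(!(a %in% c("-", ".")))
  tpos <- cumsum(!(b %in% c("-", ".")))
  pair_alignment(cbind(qpos[both], tpos[both]), raw[1], raw[2])
}

#' Read and write the package distogram format
#'
#' A text format: header line `#DGRAM n=<N> edges=<e1,e2,...>`, then one line
#' per upper-triangle (or full) residue pair: `i j p1 p2 ... p_nbins` with
#' 1-based indices. Missing (i, j) lines are filled from (j, i); diagonal
#' lines may be omitted (a one-hot on the first bin is assumed).
#'
#' @param path file path.
#' @param dg a [distogram()] (writer only).
#' @return `read_distogram` returns a [distogram()]; `write_distogram`
#'   returns `path` invisibly.
#' @rdname distogram-io
#' @export
read_distogram <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#DGRAM"))
    stop_format("line 1: missing #DGRAM header")
  hdr <- lines[1]
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  edges_txt <- sub(".*edges=([-0-9.,eE+]+).*", "\\1", hdr)
  edges <- as.numeric(strsplit(edges_txt, ",")[[1]])
  if (is.na(n) || anyNA(edges))
    stop_format("line 1: malformed #DGRAM header")
  nb <- length(edges) + 1
  probs <- array(NA_real_, c(n, n, nb))
  for (ln in seq_along(lines)[-1]) {
    txt <- trimws(lines[ln])
    if (txt == "" || startsWith(txt, "#")) next
    f <- as.numeric(strsplit(txt, "[[:space:]]+")[[1]])
    if (length(f) != nb + 2 || anyNA(f))
      stop_format("line %d: expected 'i j' plus %d probabilities", ln, nb)
    i <- as.integer(f[1]); j <- as.integer(f[2])
    if (i < 1 || j < 1 || i > n || j > n)
      stop_format("line %d: indices out of range", ln)
    probs[i, j, ] <- f[-(1:2)]
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (all(is.na(probs[i, j, ])) && !all(is.na(probs[j, i, ])))
      probs[i, j, ] <- probs[j, i, ]
  }
  for (i in seq_len(n)) if (all(is.na(probs[i, i, ])))
    probs[i, i, ] <- c(1, rep(0, nb - 1))
  if (anyNA(probs)) stop_format("missing (i, j) rows in distogram file")
  distogram(edges, probs)
}

#' @rdname distogram-io
#' @export
write_distogram <- function(dg, path) {
  stopifnot(inherits(dg, "distogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#DGRAM n=%d edges=%s", dg$n,
                     paste(format(dg$bin_edges, trim = TRUE, digits = 15),
                           collapse = ",")), con)
  for (i in seq_len(dg$n)) for (j in i:dg$n)
    writeLines(paste(c(i, j, format(dg$probs[i, j, ], trim = TRUE,
                                    digits = 17)), collapse = " "), con)
  invisible(path)
}

#' Read and write a plain mode-distance matrix
#'
#' Whitespace-separated n x n matrix of distances in Angstrom.
#'
#' @param path file path.
#' @param m a [mode_distance_matrix()] (writer only).
#' @return `read_mode_matrix` returns a [mode_distance_matrix()].
#' @rdname mode-matrix-io
#' @export
read_mode_matrix <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  d <- tryCatch(as.matrix(utils::read.table(path)),
                error = function(e) stop_format("cannot parse matrix %s: %s",
                                                path, conditionMessage(e)))
  dimnames(d) <- NULL
  if (nrow(d) != ncol(d))
    stop_format("matrix in %s is %d x %d, expected square", path, nrow(d), ncol(d))
  tryCatch(mode_distance_matrix(d),
           foldeval_validation_error = function(e)
             stop_format("%s: %s", path, conditionMessage(e)))
}

#' @rdname mode-matrix-io
#' @export
write_mode_matrix <- function(m, path) {
  stopifnot(inherits(m, "mode_distance_matrix"))
  utils::write.table(format(m$d, digits = 17, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric table from CSV
#'
#' Expects the header `group,domain,metric,value`; duplicate
#' (group, domain, metric) keys are an error.
#'
#' @param path CSV file path.
#' @param higher_better optional orientation overrides, see [metric_table()].
#' @return a [metric_table()].
#' @export
read_metric_csv <- function(path, higher_better = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE),
                 error = function(e) stop_format("cannot parse CSV %s: %s",
                                                 path, conditionMessage(e)))
  if (!all(c("group", "domain", "metric", "value") %in% names(df)))
    stop_format("%s: header must be group,domain,metric,value", path)
  tryCatch(metric_table(df, higher_better),
           foldeval_validation_error = function(e)
             stop_format("%s: %s", path, conditionMessage(e)))
}

#' Read a secondary-structure string
#'
#' A single line over the DSSP 8-state alphabet {H, G, I, E, B, T, S, -}.
#'
#' @param path file path.
#' @return character vector of per-residue single-letter labels.
#' @export
read_ss <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, ">")]
  if (length(lines) != 1)
    stop_format("%s: expected a single secondary-structure line", path)
  labels <- strsplit(lines, "")[[1]]
  bad <- which(!(labels %in% SS8_ALPHABET))
  if (length(bad))
    stop_format("%s: illegal secondary-structure character '%s' at column %d",
                path, labels[bad[1]], bad[1])
  labels
}

#' Read a per-residue probability matrix
#'
#' Whitespace-separated rows of per-class probabilities (one residue per
#' line), used for secondary-structure (8 columns) and side-chain-confidence
#' (50 columns) predictions.
#'
#' @param path file path.
#' @param n_classes required number of columns.
#' @return numeric matrix.
#' @export
read_prob_matrix <- function(path, n_classes) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  p <- tryCatch(as.matrix(utils::read.table(path)),
                error = function(e) stop_format("cannot parse %s: %s",
                                                path, conditionMessage(e)))
  dimnames(p) <- NULL
  if (ncol(p) != n_classes)
    stop_format("%s: expected %d probability columns, found %d",
                path, n_classes, ncol(p))
  p
}

#' Write a report as TSV or JSON
#'
#' @param x a data.frame (TSV) or any list/data.frame (JSON).
#' @param path output path; the format follows `format`.
#' @param format "tsv" or "json".
#' @return `path` invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a structure as a minimal PDB file
#'
#' Fixture-oriented writer (via bio3d) used by the `simulate` subcommand so
#' generated peptides can be fed back through [read_structure()].
#'
#' @param s a `structure_model`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  ap <- atom_points(s)
  resno <- vapply(s$residues, function(r) r$index, 1L)
  resid <- vapply(s$residues, function(r) r$name, "")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(ap$points)),
                   resno = resno[ap$residue],
                   resid = resid[ap$residue],
                   elety = ap$atom,
                   chain = rep(s$chain_id, length(ap$atom)))
  invisible(path)
}
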