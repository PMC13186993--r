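#' @importFrom stats complete.cases cor mad median p.adjust pt quantile
#'   rbinom rnorm runif sd setNames var
#' @importFrom utils combn read.delim write.table
NULL

SIM_COLS <- c("query", "target", "score", "qcov", "tcov", "evalue")

TAX_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
               "subfamily", "genus", "species")

#' Build a validated table of pairwise similarity edges
#'
#' Edges carry a score in `[0, 1]` (sequence-identity fraction or TM-score,
#' depending on `kind`), bidirectional coverage fractions and an e-value, the
#' tabular convention of the usual sequence/structure search tools.
#'
#' @param query,target Character vectors of protein identifiers.
#' @param score Numeric in `[0, 1]`.
#' @param qcov,tcov Coverage of the query / target, numeric in `[0, 1]`.
#' @param evalue Non-negative numeric. Defaults to 0.
#' @param kind `"sequence"` or `"structure"`.
#' @return A `data.frame` with class `gv_edges` and columns
#'   `query, target, score, qcov, tcov, evalue, kind`. Self-edges are kept but
#'   flagged in attribute `n_self_edges`.
#' @export
similarity_edges <- function(query, target, score, qcov, tcov,
                             evalue = 0, kind = c("sequence", "structure")) {
  kind <- match.arg(kind)
  n <- length(query)
  df <- data.frame(query = as.character(query), target = as.character(target),
                   score = rep_len(as.numeric(score), n),
                   qcov = rep_len(as.numeric(qcov), n),
                   tcov = rep_len(as.numeric(tcov), n),
                   evalue = rep_len(as.numeric(evalue), n),
                   kind = rep_len(kind, n),
                   stringsAsFactors = FALSE)
  validate_edges(df)
}

validate_edges <- function(df, lines = NULL) {
  where <- function(bad) {
    if (is.null(lines)) paste("row", which(bad)[1])
    else paste("line", lines[which(bad)[1]])
  }
  for (col in c("score", "qcov", "tcov")) {
    bad <- !is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1
    if (any(bad))
      stop(sprintf("similarity table: '%s' outside [0,1] at %s",
                   col, where(bad)), call. = FALSE)
  }
  bad <- !is.finite(df$evalue) | df$evalue < 0
  if (any(bad))
    stop(sprintf("similarity table: negative or non-finite evalue at %s",
                 where(bad)), call. = FALSE)
  attr(df, "n_self_edges") <- sum(df$query == df$target)
  class(df) <- c("gv_edges", "data.frame")
  df
}

#' Read a pairwise similarity table
#'
#' Accepts tab-separated tables with or without a header line. With a header,
#' columns are matched by name (`query, target, score, qcov, tcov, evalue`);
#' without one, by position in that order. Identifiers are case-sensitive
#' opaque strings. Rows are never silently dropped; malformed rows abort with
#' the offending line number.
#'
#' @param path Path to a TSV file.
#' @param kind Edge kind, `"sequence"` or `"structure"`.
#' @param col_map Optional named integer vector remapping positional columns,
#'   e.g. `c(query = 2, target = 1, ...)`.
#' @return A `gv_edges` data frame (zero rows for a header-only table).
#' @export
read_similarity_table <- function(path, kind = c("sequence", "structure"),
                                  col_map = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(similarity_edges(character(), character(), numeric(),
                            numeric(), numeric(), numeric(), kind))
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- all(c("query", "target") %in% tolower(first))
  body <- if (has_header) lines[-1] else lines
  body_lines <- if (has_header) seq_along(lines)[-1] else seq_along(lines)
  if (length(body) == 0)
    return(similarity_edges(character(), character(), numeric(),
                            numeric(), numeric(), numeric(), kind))
  cells <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(cells)
  if (any(nf < 6))
    stop(sprintf("similarity table: fewer than 6 fields at line %d",
                 body_lines[which(nf < 6)[1]]), call. = FALSE)
  m <- do.call(rbind, lapply(cells, `[`, seq_len(6)))
  idx <- seq_len(6)
  if (has_header) {
    pos <- match(SIM_COLS, tolower(first))
    if (anyNA(pos))
      stop("similarity table header missing columns: ",
           paste(SIM_COLS[is.na(pos)], collapse = ", "), call. = FALSE)
    m <- do.call(rbind, lapply(cells, `[`, pos))
  } else if (!is.null(col_map)) {
    idx <- col_map[SIM_COLS]
    m <- do.call(rbind, lapply(cells, `[`, idx))
  }
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- is.na(v)
    if (any(bad))
      stop(sprintf("similarity table: non-numeric value at line %d",
                   body_lines[which(bad)[1]]), call. = FALSE)
    v
  }
  df <- data.frame(query = m[, 1], target = m[, 2], score = num(3),
                   qcov = num(4), tcov = num(5), evalue = num(6),
                   kind = kind, stringsAsFactors = FALSE)
  validate_edges(df, lines = body_lines)
}

#' Write a similarity table
#'
#' Numeric fields are written at 6 significant digits so a write-then-read
#' round trip preserves values at that precision.
#'
#' @param edges A `gv_edges` data frame.
#' @param path Output TSV path.
#' @export
write_similarity_table <- function(edges, path) {
  out <- data.frame(query = edges$query, target = edges$target,
                    score = fmt6(edges$score), qcov = fmt6(edges$qcov),
                    tcov = fmt6(edges$tcov), evalue = fmt6(edges$evalue))
  names(out) <- SIM_COLS
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(x) trimws(formatC(signif(x, 6), format = "g", digits = 6))

#' Read a genome taxonomy table
#'
#' One genome per row with the eight ranks superkingdom..species plus a
#' virion-shape column (`icosahedral`, `non_icosahedral` or `unknown`).
#' Empty rank cells are recorded as absent (`NA`); species must be present
#' for every genome and genome identifiers must be unique.
#'
#' @param path Path to a TSV with header
#'   `genome_id, superkingdom, ..., species, shape`.
#' @return A `data.frame` of class `gv_taxonomy`.
#' @export
read_taxonomy_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                   colClasses = "character")
  names(df) <- tolower(names(df))
  need <- c("genome_id", TAX_RANKS, "shape")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxonomy table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, need]
  as_taxonomy(df)
}

#' Construct a taxonomy table from a data frame
#' @param df Data frame with columns `genome_id`, the eight ranks and `shape`.
#' @return A validated `gv_taxonomy` data frame.
#' @export
as_taxonomy <- function(df) {
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id in taxonomy table: ",
         df$genome_id[duplicated(df$genome_id)][1], call. = FALSE)
  if (any(is.na(df$species) | df$species == ""))
    stop("taxonomy table: species is required for every genome", call. = FALSE)
  df$shape[is.na(df$shape)] <- "unknown"
  ok <- df$shape %in% c("icosahedral", "non_icosahedral", "unknown")
  if (!all(ok))
    stop("taxonomy table: invalid shape value '", df$shape[!ok][1], "'",
         call. = FALSE)
  rownames(df) <- df$genome_id
  class(df) <- c("gv_taxonomy", "data.frame")
  df
}

#' Write a taxonomy table
#' @param taxonomy A `gv_taxonomy` data frame.
#' @param path Output TSV path.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  out <- as.data.frame(taxonomy)
  out[is.na(out)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clustering membership table
#'
#' Two-column TSV `(representative_id, member_id)`, one member per line — the
#' cluster convention of the usual clustering search tools. Cluster ids are
#' the representative ids.
#'
#' @param path Path to the TSV (a header line is optional).
#' @return A `gv_clustering` object.
#' @export
read_clustering <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) && identical(tolower(unlist(df[1, ])),
                            c("representative_id", "member_id")))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2)
    stop("clustering table must have two columns", call. = FALSE)
  assignment <- setNames(df[[1]], df[[2]])
  reps <- setNames(unique(df[[1]]), unique(df[[1]]))
  new_clustering(assignment, reps)
}

#' @rdname read_clustering
#' @param clustering A `gv_clustering` object.
#' @export
write_clustering <- function(clustering, path) {
  out <- data.frame(representative_id =
                      clustering$representatives[clustering$assignment],
                    member_id = names(clustering$assignment))
  out <- out[order(out$representative_id, out$member_id), ]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix with its experimental design
#'
#' The matrix is a wide TSV (first column protein id, remaining columns
#' samples); the design TSV maps `sample_id` to `condition` (`bait` or
#' `control`, plus an optional `bait_name`). Zeros and empty cells are stored
#' as missing: an intensity of 0 in label-free MS quantification denotes
#' non-observation, not true absence of signal.
#'
#' @param matrix_path,design_path Paths to the two TSV files.
#' @param contaminants Optional character vector of contaminant protein ids,
#'   or path to a one-id-per-line file.
#' @return A `gv_abundance` object: list with `intensities` (numeric matrix,
#'   `NA` for missing), `design` (data frame) and `contaminant` (named
#'   logical).
#' @export
read_abundance_matrix <- function(matrix_path, design_path,
                                  contaminants = NULL) {
  raw <- read.delim(matrix_path, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("", "NA"))
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  names(design) <- tolower(names(design))
  contam <- if (is.null(contaminants)) character() else {
    if (length(contaminants) == 1 && file.exists(contaminants))
      readLines(contaminants) else contaminants
  }
  abundance_matrix(m, design, contaminant_ids = contam)
}

#' Construct an abundance matrix object
#'
#' @param intensities Numeric matrix, proteins x samples; zeros and `NA`s
#'   are treated as missing.
#' @param design Data frame with columns `sample_id`, `condition` and
#'   optionally `bait_name`; every matrix column must appear exactly once.
#' @param contaminant_ids Character vector of contaminant protein ids.
#' @return A `gv_abundance` list.
#' @export
abundance_matrix <- function(intensities, design, contaminant_ids = character()) {
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("design must have columns sample_id and condition", call. = FALSE)
  miss <- setdiff(colnames(intensities), design$sample_id)
  if (length(miss))
    stop("samples absent from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design", call. = FALSE)
  design <- design[match(colnames(intensities), design$sample_id), ]
  if (!all(design$condition %in% c("bait", "control")))
    stop("design conditions must be 'bait' or 'control'", call. = FALSE)
  for (cond in c("bait", "control"))
    if (!any(design$condition == cond))
      stop("design has no '", cond, "' samples", call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("negative intensity in abundance matrix", call. = FALSE)
  intensities[!is.na(intensities) & intensities == 0] <- NA_real_
  structure(list(intensities = intensities, design = design,
                 contaminant = setNames(rownames(intensities) %in%
                                          contaminant_ids,
                                        rownames(intensities)),
                 log2 = FALSE),
            class = "gv_abundance")
}

#' @export
print.gv_abundance <- function(x, ...) {
  cat(sprintf("gv_abundance: %d proteins x %d samples (%d bait, %d control)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$design$condition == "bait"),
              sum(x$design$condition == "control")))
  cat(sprintf("  missing cells: %d; contaminants flagged: %d; scale: %s\n",
              sum(is.na(x$intensities)), sum(x$contaminant),
              if (x$log2) "log2" else "raw"))
  invisible(x)
}

#' Write an abundance matrix and its design
#' @param x A `gv_abundance` object.
#' @param matrix_path,design_path Output TSV paths.
#' @export
write_abundance_matrix <- function(x, matrix_path, design_path) {
  m <- x$intensities
  out <- data.frame(protein_id = rownames(m),
                    apply(m, 2, fmt6), check.names = FALSE)
  out[out == "NA"] <- ""
  write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Readers for the auxiliary annotation tables
#'
#' Small TSV readers for per-predictor transmembrane calls
#' (`protein, phobius, deeptmhmm, tmbed` as 0/1), region labels
#' (`protein, region`), expression clusters (`protein, cluster`), spectral
#' counts (`protein, peptides, nucleoid_pellet, nucleoid_supernatant,
#' virion_pellet, virion_supernatant`), PDB hits
#' (`protein, pdb_id, chain_id, evalue, source`) and chain coordinates
#' (`pdb_id, chain_id, x, y, z` in Angstrom, one point per row).
#'
#' @param path Path to a TSV file with header.
#' @return A data frame with the columns listed above.
#' @name aux_readers
NULL

#' @rdname aux_readers
#' @export
read_predictor_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "protein")
    stop("predictor-call table must start with a 'protein' column",
         call. = FALSE)
  for (j in seq(2, ncol(df))) df[[j]] <- as.integer(df[[j]]) > 0
  df
}

#' @rdname aux_readers
#' @export
read_region_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ok <- df$region %in% c("membrane", "virion", "nucleoid", "vf_il", "host")
  if (!all(ok))
    stop("unknown region label: ", df$region[!ok][1], call. = FALSE)
  df
}

#' @rdname aux_readers
#' @export
read_spectral_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "peptides", "nucleoid_pellet", "nucleoid_supernatant",
            "virion_pellet", "virion_supernatant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spectral-count table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname aux_readers
#' @export
read_chain_points <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("chain-coordinate table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite chain coordinates", call. = FALSE)
  df
}

#' Write a network as GraphML and as an attribute edge list
#' @param graph An `igraph` graph.
#' @param graphml_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_network <- function(graph, graphml_path = NULL, tsv_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(tsv_path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    write.table(el, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(graph)
}
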