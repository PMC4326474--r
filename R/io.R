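#' Read a protein-protein association file
#'
#' Parses the STRING `protein.links` dialect: one association per line, two
#' node identifiers followed by an integer combined score on the 0-999 scale
#' (confidence 0.800 is stored as 800).  Space- or tab-separated; an optional
#' header line whose first field starts with "protein1" is skipped.  Edges
#' below the score threshold are discarded, duplicates and reversed
#' duplicates collapse to one undirected edge, self-loops are dropped with a
#' warning, and nodes left without any edge are excluded: a gene with no
#' association cannot be seriated.
#'
#' @param path file path.
#' @param score_min minimum combined score kept.  Either an integer in
#'   0..999 or a confidence in (0, 1), which is mapped to the integer scale
#'   (0.800 -> 800).
#' @return An [interaction_network()].
#' @export
read_interactions <- function(path, score_min = 800) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (length(score_min) != 1 || is.na(score_min) || score_min < 0)
    abort("`score_min` must be a single value in [0, 999] or (0, 1)")
  if (score_min > 0 && score_min < 1) score_min <- as.integer(round(1000 * score_min))
  if (score_min > 999) abort("`score_min` must be <= 999")

  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) && grepl("^protein1", trimws(lines[rows[1]]))) rows <- rows[-1]

  a <- character(0); b <- character(0); s <- integer(0)
  for (ln in rows) {
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(fields) < 3)
      parse_abort(path, ln, sprintf("expected >= 3 fields, got %d", length(fields)))
    sc <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(sc) || sc != as.integer(sc))
      parse_abort(path, ln, sprintf("score '%s' is not an integer", fields[3]))
    if (sc < 0 || sc > 999)
      abort(sprintf("%s:%d: score %d outside [0, 999]", path, ln, as.integer(sc)),
            class = "xgram_invalid_score")
    if (sc >= score_min) {
      a <- c(a, fields[1]); b <- c(b, fields[2]); s <- c(s, as.integer(sc))
    }
  }
  if (!length(a)) {
    warn("no associations at or above the score threshold")
    return(structure(list(nodes = character(0),
                          edges = matrix(integer(0), 0, 2),
                          degree = setNames(integer(0), character(0))),
                     class = "interaction_network"))
  }
  interaction_network(data.frame(a, b))
}

#' Read a genes-by-samples expression table
#'
#' Expects a TSV with a header row of sample IDs and gene IDs in the first
#' column; values are pre-normalized (log2-scale, e.g. RMA output).  Rows
#' sharing a gene ID -- multiple probe sets per gene are the norm on arrays --
#' are collapsed by their arithmetic mean, with a message reporting how many.
#'
#' @param path file path.
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("expression table needs a gene column plus >= 1 sample")
  samples <- names(raw)[-1]
  if (anyDuplicated(samples))
    abort(sprintf("duplicate sample ID '%s' in header",
                  samples[duplicated(samples)][1]),
          class = "xgram_invalid_design")
  genes <- raw[[1]]
  vals <- as.data.frame(raw[-1])
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      abort(sprintf("%s: non-numeric value '%s' at gene row %d (gene '%s'), sample '%s'",
                    path, vals[[j]][bad[1]], bad[1], genes[bad[1]], samples[j]),
            class = "xgram_parse_error")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    inform(sprintf("collapsed %d duplicate gene row(s) by mean", n_dup))
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  names(out) <- samples
  dplyr::bind_cols(tibble(gene = genes), out)
}

#' Read a sample design table
#'
#' TSV with columns `sample`, `condition`, `bio_rep`, `tech_rep` describing
#' the replicate structure: `bio_rep` indexes biological replicates within a
#' condition and `tech_rep` indexes repeated measurements of the same
#' biological sample.
#'
#' @param path file path.
#' @return A tibble with columns `sample`, `condition`, `bio_rep`, `tech_rep`.
#' @export
read_design <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "condition", "bio_rep", "tech_rep")
  if (!all(need %in% names(d)))
    abort(sprintf("design table must have columns %s", paste(need, collapse = ", ")),
          class = "xgram_invalid_design")
  d <- as_tibble(d[need])
  d$bio_rep <- as.integer(d$bio_rep)
  d$tech_rep <- as.integer(d$tech_rep)
  validate_design(d)
}

validate_design <- function(design) {
  design <- as_tibble(design)
  if (anyDuplicated(design$sample))
    abort("duplicate sample IDs in design", class = "xgram_invalid_design")
  key <- paste(design$condition, design$bio_rep, design$tech_rep)
  if (anyDuplicated(key))
    abort("duplicate (condition, bio_rep, tech_rep) triple in design",
          class = "xgram_invalid_design")
  design
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then the member gene IDs, all
#' tab-separated.  Duplicate members within a line are dropped.
#'
#' @param path file path.
#' @return A tibble with columns `name`, `description` and list-column
#'   `genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(tibble(name = character(0), description = character(0),
                  genes = list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts))
    if (length(parts[[i]]) < 3)
      parse_abort(path, i, "GMT line needs name, description and >= 1 member")
  tibble(
    name = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write / read an ordering file
#'
#' The on-disk layout is one row per list position: position, gene name,
#' protein ID, relative position, then any per-position statistics columns
#' supplied in `stats` (P-values, q-values, ...).  On read, positions must be
#' consecutive 1..N and relative positions are recomputed from N rather than
#' trusted from the file.
#'
#' @param ordering a [gene_ordering()].
#' @param path file path.
#' @param stats optional data frame of per-position columns to append.
#' @param protein_id optional character vector of protein IDs (defaults to
#'   the gene IDs).
#' @return `write_ordering()` returns `path` invisibly; `read_ordering()`
#'   returns a `gene_ordering` whose extra columns, if any, are kept as an
#'   attribute `stats`.
#' @export
write_ordering <- function(ordering, path, stats = NULL, protein_id = NULL) {
  ord <- validate_ordering(ordering)
  out <- data.frame(
    position = ord$position,
    gene_name = ord$gene,
    protein_id = protein_id %||% ord$gene,
    rel_position = ord$rel_position
  )
  if (!is.null(stats)) {
    stats <- as.data.frame(stats)
    if (nrow(stats) != nrow(out))
      abort("`stats` must have one row per ordering position")
    out <- cbind(out, stats)
  }
  con <- file(path, open = "wb") # LF line endings on every platform
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_ordering
#' @export
read_ordering <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("position", "gene_name") %in% names(d)))
    abort("ordering file must have 'position' and 'gene_name' columns")
  d <- d[order(d$position), ]
  if (!identical(as.integer(d$position), seq_len(nrow(d))))
    abort("ordering file positions are not consecutive 1..N",
          class = "xgram_bad_ordering")
  ord <- gene_ordering(d$gene_name)
  extra <- setdiff(names(d), c("position", "gene_name", "protein_id", "rel_position"))
  if (length(extra)) attr(ord, "stats") <- as_tibble(d[extra])
  ord
}
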