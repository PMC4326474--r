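# -- windowed expression profiles along a seriated gene list ----------------

# wide tibble (gene + sample columns) -> numeric matrix, genes as rownames
expr_matrix <- function(expression) {
  if (is.matrix(expression)) return(expression)
  expression <- as.data.frame(expression)
  if (!"gene" %in% names(expression))
    abort("expression table must have a `gene` column")
  m <- as.matrix(expression[setdiff(names(expression), "gene")])
  rownames(m) <- expression$gene
  storage.mode(m) <- "double"
  m
}

# align a genes-x-samples matrix onto ordering positions; rows become
# positions 1..N, theta marks positions whose gene was measured
align_to_ordering <- function(m, ordering, quiet = FALSE) {
  ord <- validate_ordering(ordering)
  hit <- rownames(m) %in% ord$gene
  if (!any(hit))
    abort("no overlap between expression genes and the ordering",
          class = "xgram_no_overlap")
  if (any(!hit) && !quiet)
    inform(sprintf("%d gene(s) not in the ordering were dropped (kept in the unmapped list)",
                   sum(!hit)))
  idx <- match(ord$gene, rownames(m))
  aligned <- matrix(NA_real_, nrow(ord), ncol(m),
                    dimnames = list(ord$gene, colnames(m)))
  aligned[!is.na(idx), ] <- m[idx[!is.na(idx)], , drop = FALSE]
  list(values = aligned, theta = as.integer(!is.na(idx)), ordering = ord,
       unmapped = rownames(m)[!hit])
}

#' Box-car profile of a single expression vector
#'
#' The elementary windowing step: each list position is assigned the average
#' expression over the `2r + 1` positions centred on it (truncated at the
#' list ends), counting only positions whose gene was actually measured
#' (coverage mask theta).  At `r = 0` the profile is just the measured
#' values laid out along the ordering -- a transcriptome.
#'
#' @param values named numeric vector (names = gene IDs) or a two-column
#'   data frame (gene, value).
#' @param ordering a [gene_ordering()].
#' @param r window radius (integer >= 0).
#' @return A tibble with columns `position`, `rel_position`, `gene`, `theta`,
#'   `value`; positions whose whole window is uncovered are `NA`.
#' @export
boxcar_profile <- function(values, ordering, r) {
  if (is.data.frame(values)) {
    v <- values[[2]]
    names(v) <- values[[1]]
    values <- v
  }
  m <- matrix(values, ncol = 1, dimnames = list(names(values), "value"))
  al <- align_to_ordering(m, ordering)
  out <- boxcar_masked(al$values[, 1], al$theta, r)
  tibble(position = al$ordering$position,
         rel_position = al$ordering$rel_position,
         gene = al$ordering$gene,
         theta = al$theta, value = out)
}

#' Transcriptograms for every sample of an expression table
#'
#' Applies the theta-masked box-car of [boxcar_profile()] to each sample
#' column.  Smoothing happens per sample (before any averaging across
#' replicates), which is the faithful treatment when some ordering positions
#' are uncovered by the platform.
#'
#' @param expression tibble with a `gene` column plus one numeric column per
#'   sample (as from [read_expression()]).
#' @param ordering a [gene_ordering()].
#' @param r window radius.
#' @return A long tibble `position`, `rel_position`, `gene`, `theta`,
#'   `sample`, `value`, carrying the radius and the unmapped-gene list as
#'   attributes `r` and `unmapped`.
#' @export
transcriptogram <- function(expression, ordering, r) {
  tg <- tg_matrix(expression, ordering, r)
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(position = tg$ordering$position,
                            rel_position = tg$ordering$rel_position,
                            gene = tg$ordering$gene,
                            theta = tg$theta),
                     as_tibble(as.data.frame(tg$values, check.names = FALSE))),
    cols = -(1:4), names_to = "sample", values_to = "value"
  )
  attr(long, "r") <- r
  attr(long, "unmapped") <- tg$unmapped
  long
}

# positions-x-samples matrix of smoothed values (internal workhorse)
tg_matrix <- function(expression, ordering, r, quiet = FALSE) {
  al <- align_to_ordering(expr_matrix(expression), ordering, quiet = quiet)
  sm <- apply(al$values, 2, boxcar_masked, theta = al$theta, r = r)
  sm <- matrix(sm, nrow = nrow(al$values), dimnames = dimnames(al$values))
  list(values = sm, theta = al$theta, ordering = al$ordering,
       unmapped = al$unmapped)
}

#' Per-condition average transcriptograms
#'
#' Each sample is smoothed individually, then samples of a condition are
#' averaged position-wise; the spread across a condition's replicate
#' transcriptograms gives the per-position SD and standard error.
#'
#' @inheritParams transcriptogram
#' @param design design tibble (`sample`, `condition`, `bio_rep`,
#'   `tech_rep`), see [read_design()].
#' @param conditions optional subset of condition labels (default: all).
#' @return A tibble `position`, `rel_position`, `condition`, `mean`, `sd`,
#'   `se`, `n`.
#' @export
class_profiles <- function(expression, design, ordering, r, conditions = NULL) {
  design <- validate_design(design)
  conditions <- conditions %||% unique(design$condition)
  missing_cond <- setdiff(conditions, design$condition)
  if (length(missing_cond))
    abort(sprintf("condition '%s' absent from design", missing_cond[1]),
          class = "xgram_invalid_design")
  tg <- tg_matrix(expression, ordering, r)
  purrr::map_dfr(conditions, function(k) {
    cols <- design$sample[design$condition == k]
    m <- tg$values[, cols, drop = FALSE]
    tibble(position = tg$ordering$position,
           rel_position = tg$ordering$rel_position,
           condition = k,
           mean = unname(rowMeans(m)),
           sd = unname(sqrt(row_vars(m))),
           se = unname(sqrt(row_vars(m)) / sqrt(ncol(m))),
           n = ncol(m))
  })
}

#' Relative average transcriptograms
#'
#' For each biological replicate of each condition, the mean over its
#' technical replicates is divided position-wise by the mean transcriptogram
#' of the reference class (all its samples pooled).  Values are ratios of
#' (log2-scale) window averages, not differences; the reference class
#' averages to 1 against itself.  Positions where the reference is zero or
#' negative are flagged missing rather than divided through.
#'
#' @inheritParams class_profiles
#' @param reference condition label used as the denominator class.
#' @return A tibble `position`, `rel_position`, `condition`, `bio_rep`,
#'   `n_tech`, `value`.
#' @export
relative_profile <- function(expression, design, ordering, r, reference) {
  design <- validate_design(design)
  if (!reference %in% design$condition)
    abort(sprintf("reference condition '%s' absent from design", reference),
          class = "xgram_invalid_design")
  tg <- tg_matrix(expression, ordering, r)
  ref_cols <- design$sample[design$condition == reference]
  ref <- rowMeans(tg$values[, ref_cols, drop = FALSE])
  ref[!is.na(ref) & ref <= 0] <- NA_real_
  groups <- dplyr::distinct(design, .data$condition, .data$bio_rep)
  purrr::pmap_dfr(groups, function(condition, bio_rep) {
    cols <- design$sample[design$condition == condition &
                            design$bio_rep == bio_rep]
    tibble(position = tg$ordering$position,
           rel_position = tg$ordering$rel_position,
           condition = condition, bio_rep = bio_rep,
           n_tech = length(cols),
           value = unname(rowMeans(tg$values[, cols, drop = FALSE]) / ref))
  })
}

#' Project a gene set onto the ordering
#'
#' Assigns 1 to positions whose gene belongs to the set and 0 elsewhere,
#' then smooths the indicator with the same truncated box-car used for
#' expression (full coverage).  Peaks of the profile mark intervals of the
#' ordering enriched for the set, which is how GO terms and KEGG pathways
#' are located along the list.
#'
#' @param genes character vector of member gene IDs (zero overlap with the
#'   ordering is allowed and logged).
#' @inheritParams boxcar_profile
#' @return A tibble `position`, `rel_position`, `gene`, `indicator`,
#'   `value`, with values in [0, 1].
#' @export
project_gene_set <- function(genes, ordering, r) {
  ord <- validate_ordering(ordering)
  genes <- unique(as.character(genes))
  ind <- as.integer(ord$gene %in% genes)
  if (!sum(ind)) inform("gene set has no overlap with the ordering")
  tibble(position = ord$position, rel_position = ord$rel_position,
         gene = ord$gene, indicator = ind,
         value = boxcar_masked(ind, rep(1L, nrow(ord)), r))
}

#' @describeIn project_gene_set Project every set of a GMT table (from
#'   [read_gene_sets()]); returns the same layout with an extra `name`
#'   column.
#' @param sets tibble with `name` and list-column `genes`.
#' @export
project_gene_sets <- function(sets, ordering, r) {
  purrr::map2_dfr(sets$name, sets$genes, function(nm, g)
    dplyr::mutate(project_gene_set(g, ordering, r), name = nm,
                  .before = 1))
}

#' Variance components of the replicate design
#'
#' Decomposes per-gene variability into the technical component (variance
#' across technical replicates, pooled within biological replicates) and the
#' biological component (variance across biological-replicate means, with
#' the technical contribution `sigma2_xi / n_a` subtracted and floored at
#' zero).  The window-level term `kappa_bar` -- the mean covariance of
#' biological variation over gene pairs inside each window -- decides
#' whether windowing shrinks biological noise: it vanishes when genes vary
#' independently and equals the biological variance when the whole window
#' moves together.
#'
#' @inheritParams class_profiles
#' @param r window radius used for `kappa_bar`.
#' @return An object of class `variance_components`: list with `genes`
#'   (tibble `gene`, `sigma2_xi`, `sigma2_b`), `positions` (tibble
#'   `position`, `kappa_bar`, `mean_bio_var`), and `summary` (pooled means).
#' @export
decompose_variance <- function(expression, design, ordering, r = 80) {
  design <- validate_design(design)
  m <- expr_matrix(expression)
  m <- m[, design$sample, drop = FALSE]

  cells <- dplyr::distinct(design, .data$condition, .data$bio_rep)
  cell_cols <- purrr::pmap(cells, function(condition, bio_rep)
    design$sample[design$condition == condition & design$bio_rep == bio_rep])
  n_a_per_cell <- lengths(cell_cols)
  if (!any(n_a_per_cell >= 2))
    abort("need >= 2 technical replicates in at least one biological replicate to estimate technical variance",
          class = "xgram_insufficient_replication")

  # technical variance: pooled across (condition, bio rep) cells
  ss <- 0; df <- 0
  ss_gene <- numeric(nrow(m)); df_gene <- 0
  for (cols in cell_cols[n_a_per_cell >= 2]) {
    v <- row_vars(m[, cols, drop = FALSE])
    ss_gene <- ss_gene + v * (length(cols) - 1)
    df_gene <- df_gene + (length(cols) - 1)
  }
  sigma2_xi <- ss_gene / df_gene

  # biological variance from the spread of bio-rep means within condition
  conds <- unique(design$condition)
  n_b_per_cond <- vapply(conds, function(k)
    dplyr::n_distinct(design$bio_rep[design$condition == k]), integer(1))
  if (!any(n_b_per_cond >= 2))
    abort("need >= 2 biological replicates in at least one condition to estimate biological variance",
          class = "xgram_insufficient_replication")

  sigma2_b_acc <- numeric(nrow(m)); b_conds <- 0
  kappa_acc <- NULL; bio_var_acc <- NULL
  ord <- validate_ordering(ordering)
  for (k in conds[n_b_per_cond >= 2]) {
    sub <- design[design$condition == k, ]
    breps <- sort(unique(sub$bio_rep))
    bm <- vapply(breps, function(b)
      rowMeans(m[, sub$sample[sub$bio_rep == b], drop = FALSE]), numeric(nrow(m)))
    na_bar <- mean(vapply(breps, function(b)
      sum(sub$bio_rep == b), integer(1)))
    v_between <- row_vars(bm)
    sigma2_b_acc <- sigma2_b_acc + pmax(v_between - sigma2_xi / na_bar, 0)
    b_conds <- b_conds + 1

    # windowed mean off-diagonal covariance of biological-replicate means:
    # sum of all pairwise covariances in a window equals the variance of the
    # window sum, so kappa_bar falls out of two sliding sums
    al <- align_to_ordering(bm, ord, quiet = TRUE)
    bw <- al$values
    bw[al$theta == 0, ] <- 0
    win_sum <- apply(bw, 2, function(col) {
      cs <- cumsum(c(0, col))
      i <- seq_len(nrow(bw))
      cs[pmin(nrow(bw), i + r) + 1L] - cs[pmax(1L, i - r)]
    })
    var_sum <- row_vars(win_sum)
    vb <- ifelse(al$theta == 1, v_between[match(ord$gene, rownames(m))], 0)
    vb[is.na(vb)] <- 0
    cs_v <- cumsum(c(0, vb))
    cs_t <- cumsum(c(0, al$theta))
    i <- seq_len(nrow(ord))
    sum_var <- cs_v[pmin(nrow(ord), i + r) + 1L] - cs_v[pmax(1L, i - r)]
    w_eff <- cs_t[pmin(nrow(ord), i + r) + 1L] - cs_t[pmax(1L, i - r)]
    kap <- ifelse(w_eff >= 2, (var_sum - sum_var) / (w_eff * (w_eff - 1)), NA_real_)
    mbv <- ifelse(w_eff >= 1, sum_var / w_eff, NA_real_)
    kappa_acc <- if (is.null(kappa_acc)) kap else kappa_acc + kap
    bio_var_acc <- if (is.null(bio_var_acc)) mbv else bio_var_acc + mbv
  }
  sigma2_b <- sigma2_b_acc / b_conds

  structure(
    list(genes = tibble(gene = rownames(m),
                        sigma2_xi = sigma2_xi, sigma2_b = sigma2_b),
         positions = tibble(position = ord$position,
                            kappa_bar = kappa_acc / b_conds,
                            mean_bio_var = bio_var_acc / b_conds),
         summary = list(sigma2_xi = mean(sigma2_xi, na.rm = TRUE),
                        sigma2_b = mean(sigma2_b, na.rm = TRUE),
                        r = r)),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> mean sigma2_xi = %.4g, mean sigma2_b = %.4g (r = %d)\n",
              x$summary$sigma2_xi, x$summary$sigma2_b, x$summary$r))
  invisible(x)
}
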