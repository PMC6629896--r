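#' Mann-Whitney screening of a feature table
#'
#' Two-sided rank-sum test per index between two groups. The exact null
#' distribution is used when both groups have at most 8 non-missing values
#' and no ties; otherwise the normal approximation with tie correction.
#' Significance tiers: `"*"` for p <= `alpha` (0.01), `"**"` for
#' p <= `alpha/10`, `"***"` for p <= `alpha/m` (Bonferroni over the m indices
#' tested), `"n.s."` otherwise. Indices constant across both groups get
#' p = 1.
#'
#' @param table feature `data.frame` from [cohort_features()] (columns
#'   `subject_id`, `group`, indices).
#' @param group_a,group_b group labels to compare.
#' @param alpha base significance level (default 0.01).
#' @param min_per_group minimal non-missing values per group for an index to
#'   be tested (default 3).
#' @return An object of class `screen_result`: `data.frame` `stats` with
#'   columns `index`, `U`, `p`, `tier`, `kept`; plus `alpha`, `m`,
#'   `bonferroni` (= alpha/m), and the group labels.
#' @export
mwu_screen <- function(table, group_a, group_b, alpha = 0.01,
                       min_per_group = 3L) {
  ga <- table$group == group_a
  gb <- table$group == group_b
  if (!any(ga) || !any(gb))
    stop("both groups must be present in the table", call. = FALSE)
  idx_cols <- setdiff(names(table), c("subject_id", "group"))
  res <- lapply(idx_cols, function(cn) {
    xa <- table[[cn]][ga]; xb <- table[[cn]][gb]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < min_per_group || length(xb) < min_per_group)
      return(data.frame(index = cn, U = NA_real_, p = NA_real_,
                        tier = "n.s.", stringsAsFactors = FALSE))
    if (stats::sd(c(xa, xb)) == 0)
      return(data.frame(index = cn, U = length(xa) * length(xb) / 2, p = 1,
                        tier = "n.s.", stringsAsFactors = FALSE))
    exact <- length(xa) <= 8L && length(xb) <= 8L &&
      !any(duplicated(c(xa, xb)))
    wt <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = exact, correct = !exact))
    data.frame(index = cn, U = unname(wt$statistic), p = wt$p.value,
               tier = "n.s.", stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, res)
  m <- sum(!is.na(stats_df$p))
  bonf <- alpha / m
  p <- stats_df$p
  stats_df$tier <- ifelse(is.na(p), "n.s.",
                   ifelse(p <= bonf, "***",
                   ifelse(p <= alpha / 10, "**",
                   ifelse(p <= alpha, "*", "n.s."))))
  stats_df$kept <- stats_df$tier != "n.s."
  structure(list(stats = stats_df, alpha = alpha, m = m, bonferroni = bonf,
                 group_a = group_a, group_b = group_b),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s vs %s: %d indices tested, %d significant (Bonferroni cut %.3g)\n",
              x$group_a, x$group_b, x$m, sum(x$stats$kept), x$bonferroni))
  invisible(x)
}

#' Correlation pruning of screened indices
#'
#' Among indices that passed screening, pairs with absolute Spearman rank
#' correlation at or above `rho_max` are reduced to one member: processing
#' pairs in descending absolute correlation, the index with the larger
#' screening p-value is dropped (ties broken by keeping the
#' lexicographically smaller column name). The surviving set contains no
#' pair at or above the threshold.
#'
#' @param table the feature table the screen was computed on.
#' @param screen a [mwu_screen()] result.
#' @param rho_max correlation threshold (default 0.7).
#' @return The `screen_result` with its `kept` column updated; attribute
#'   `"dropped"` on the result lists the pruned indices.
#' @export
correlation_prune <- function(table, screen, rho_max = 0.7) {
  stopifnot(inherits(screen, "screen_result"))
  st <- screen$stats
  sig <- st$index[st$kept]
  if (length(sig) < 2L) return(screen)
  sub <- table[table$group %in% c(screen$group_a, screen$group_b), sig,
               drop = FALSE]
  cm <- suppressWarnings(
    stats::cor(as.matrix(sub), method = "spearman",
               use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  pairs <- which(upper.tri(cm) & abs(cm) >= rho_max, arr.ind = TRUE)
  if (nrow(pairs) > 0L) {
    ord <- order(-abs(cm[pairs]), sig[pairs[, 1]], sig[pairs[, 2]])
    pairs <- pairs[ord, , drop = FALSE]
    pvals <- st$p[match(sig, st$index)]
    alive <- rep(TRUE, length(sig))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!alive[i] || !alive[j]) next
      drop_j <- pvals[j] > pvals[i] ||
        (pvals[j] == pvals[i] && sig[j] > sig[i])
      if (drop_j) alive[j] <- FALSE else alive[i] <- FALSE
    }
    dropped <- sig[!alive]
    st$kept[st$index %in% dropped] <- FALSE
  } else dropped <- character(0)
  screen$stats <- st
  attr(screen, "dropped") <- dropped
  screen
}

#' Indices surviving screening and pruning
#' @param screen a `screen_result`.
#' @param n optional: only the top-n by p-value.
#' @return Character vector of index names ordered by ascending p.
#' @export
kept_indices <- function(screen, n = Inf) {
  st <- screen$stats[screen$stats$kept, , drop = FALSE]
  st <- st[order(st$p, st$index), , drop = FALSE]
  utils::head(st$index, n)
}
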