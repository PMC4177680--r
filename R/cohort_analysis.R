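# Cohort analyses over retention records: size-group retention bias,
# significant-set overlaps, replicate concordance and feature association.

#' Default IES size bins
#'
#' 23 contiguous groups reconstructed from the periodic IES size
#' distribution: the five peak groups 26-32, 33-42, 43-52, 53-62, 63-72 bp,
#' width-10 groups through 203-212 bp, then 213-332, 333-532, 533-1032 and a
#' final >= 1033 bp group.
#'
#' @return `data.frame` with `group`, `lower`, `upper`, `label`.
#' @export
default_size_bins <- function() {
  lower <- c(26L, 33L, 43L, 53L, 63L, seq(73L, 203L, 10L),
             213L, 333L, 533L, 1033L)
  upper <- c(lower[-1L] - 1L, NA_integer_)
  data.frame(
    group = seq_along(lower), lower = lower, upper = upper,
    label = ifelse(is.na(upper), paste0(">=", lower),
                   paste0(lower, "-", upper)),
    stringsAsFactors = FALSE
  )
}

validate_size_bins <- function(bins) {
  stopifnot(is.data.frame(bins), all(c("lower", "upper") %in% names(bins)))
  n <- nrow(bins)
  if (n == 0L) stop("empty binning", call. = FALSE)
  if (is.unsorted(bins$lower, strictly = TRUE)) {
    stop("bin lower edges must be strictly increasing", call. = FALSE)
  }
  up <- bins$upper[-n]
  if (any(is.na(up)) || any(up != bins$lower[-1L] - 1L)) {
    stop("bins must be contiguous and non-overlapping", call. = FALSE)
  }
  if (bins$lower[1L] > 26L) {
    stop("bins must cover lengths from 26 bp", call. = FALSE)
  }
  bins
}

#' Assign IES lengths to size groups
#'
#' @param length IES length(s) in bp.
#' @param bins Binning from [default_size_bins()].
#' @return Integer group index (1-based).
#' @export
assign_size_group <- function(length, bins = default_size_bins()) {
  bins <- validate_size_bins(bins)
  if (any(length < bins$lower[1L])) {
    stop("length below the smallest bin edge (", bins$lower[1L], " bp)",
         call. = FALSE)
  }
  findInterval(length, bins$lower)
}

star_level <- function(p) {
  if (is.na(p)) "" else if (p < 2.2e-16) "***" else if (p < 1e-10) "**" else
    if (p < 0.05) "*" else ""
}

#' Per-size-group retention summaries
#'
#' Medians and quartiles of RS per size group plus a two-sided rank-sum
#' (Mann-Whitney) test of each group against the previous one. Stars encode
#' the adjacent-group p-value: `*` p < 0.05, `**` p < 1e-10,
#' `***` p < 2.2e-16.
#'
#' @param records Retention records (needs `ies_id`, `rs`, `significant`).
#' @param lengths `data.frame` with `ies_id` and `length`.
#' @param bins Size binning.
#' @return `data.frame`: group, label, n, q1, median, q3,
#'   proportion_significant, p_vs_previous, stars.
#' @export
group_summaries <- function(records, lengths, bins = default_size_bins()) {
  bins <- validate_size_bins(bins)
  len <- lengths$length[match(records$ies_id, lengths$ies_id)]
  keep <- !is.na(records$rs) & !is.na(len)
  rs <- records$rs[keep]
  sig <- records$significant[keep]
  grp <- assign_size_group(len[keep], bins)
  out <- data.frame(
    group = bins$group, label = bins$label, n = 0L,
    q1 = NA_real_, median = NA_real_, q3 = NA_real_,
    proportion_significant = NA_real_,
    p_vs_previous = NA_real_, stars = "",
    stringsAsFactors = FALSE
  )
  by_grp <- split(rs, factor(grp, levels = bins$group))
  sig_grp <- split(sig, factor(grp, levels = bins$group))
  for (i in seq_len(nrow(bins))) {
    v <- by_grp[[i]]
    out$n[i] <- length(v)
    if (length(v) == 0L) next
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    out$q1[i] <- q[1L]; out$median[i] <- q[2L]; out$q3[i] <- q[3L]
    out$proportion_significant[i] <- mean(sig_grp[[i]])
    if (i > 1L && length(by_grp[[i - 1L]]) > 0L &&
        (length(v) + length(by_grp[[i - 1L]])) > 3L) {
      exact <- length(v) <= 50L && length(by_grp[[i - 1L]]) <= 50L
      out$p_vs_previous[i] <- suppressWarnings(
        stats::wilcox.test(v, by_grp[[i - 1L]], exact = exact)$p.value)
      out$stars[i] <- star_level(out$p_vs_previous[i])
    }
  }
  out
}

#' Proportion of significantly retained IESs per size group
#'
#' @inheritParams group_summaries
#' @return `data.frame`: group, label, n, proportion.
#' @export
proportion_significant_by_group <- function(records, lengths,
                                            bins = default_size_bins()) {
  s <- group_summaries(records, lengths, bins)
  data.frame(group = s$group, label = s$label, n = s$n,
             proportion = s$proportion_significant,
             stringsAsFactors = FALSE)
}

#' Overlap cells of significant sets across samples
#'
#' Computes every exclusive intersection cell of the Venn partition over the
#' given id sets, plus pairwise subset relations.
#'
#' @param sets Named list of character vectors (e.g. significant ies_ids per
#'   knockdown).
#' @return List with `cells` (membership pattern, count) and `subsets`
#'   (pairwise `is_subset` table). Cell counts sum to the union size.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(logical(0), 0L, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  if (length(universe) == 1L) {
    member <- matrix(member, 1L, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  counts <- apply(patterns, 1L, function(pat) {
    sum(apply(member, 1L, function(row) all(row == pat)))
  })
  cells <- data.frame(
    cell = apply(patterns, 1L, function(pat) {
      paste(names(sets)[as.logical(pat)], collapse = "&")
    }),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  pairs <- expand.grid(a = names(sets), b = names(sets),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pairs$is_subset <- mapply(function(a, b) {
    all(sets[[a]] %in% sets[[b]])
  }, pairs$a, pairs$b)
  rownames(cells) <- rownames(pairs) <- NULL
  list(cells = cells, subsets = pairs)
}

#' Spearman rank correlation of two retention-score vectors
#'
#' Mid-ranks for ties; p-value from the t approximation of the rank
#' correlation.
#'
#' @param rs_a,rs_b Paired numeric vectors (NA pairs dropped).
#' @return List with `rho`, `p`, `n`.
#' @export
rank_correlation <- function(rs_a, rs_b) {
  stopifnot(length(rs_a) == length(rs_b))
  keep <- !is.na(rs_a) & !is.na(rs_b)
  a <- rs_a[keep]; b <- rs_b[keep]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(a), rank(b))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare a feature between significant and non-significant IESs
#'
#' Continuous features (e.g. GC content) are compared with a two-sided
#' rank-sum (Mann-Whitney) test; binary features (e.g. located within a gene)
#' with a chi-square test on the 2x2 table. The effect direction is reported
#' relative to the significant set.
#'
#' @param significant Feature values of the significantly retained IESs.
#' @param non_significant Feature values of the remaining IESs.
#' @param type `"continuous"` or `"binary"`.
#' @return List with `type`, `p`, `direction` and the group summaries.
#' @export
compare_feature <- function(significant, non_significant,
                            type = c("continuous", "binary")) {
  type <- match.arg(type)
  if (length(significant) == 0L || length(non_significant) == 0L) {
    stop("both sets must be non-empty", call. = FALSE)
  }
  if (type == "continuous") {
    p <- suppressWarnings(
      stats::wilcox.test(significant, non_significant)$p.value)
    m1 <- stats::median(significant); m2 <- stats::median(non_significant)
    direction <- if (p >= 0.05 || m1 == m2) "none" else
      if (m1 > m2) "higher" else "lower"
    list(type = type, p = p, direction = direction,
         median_significant = m1, median_non_significant = m2)
  } else {
    s <- as.logical(significant); ns <- as.logical(non_significant)
    tab <- rbind(significant = c(sum(s), sum(!s)),
                 non_significant = c(sum(ns), sum(!ns)))
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    p1 <- mean(s); p2 <- mean(ns)
    direction <- if (is.na(p) || p >= 0.05 || p1 == p2) "none" else
      if (p1 > p2) "higher" else "lower"
    list(type = type, p = p, direction = direction,
         prop_significant = p1, prop_non_significant = p2)
  }
}
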