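#' Unpaired two-sample t-test
#'
#' Student's equal-variance two-sample t-test (two-sided), the comparison
#' used for ipsilateral-vs-contralateral and afferent-vs-efferent count
#' totals; Welch's unequal-variance form is available via `welch`. When the
#' pooled variance is zero the convention is t = 0, p = 1 if the group
#' means are equal, else p = 0.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 finite
#'   values.
#' @param welch Use Welch's t-test instead of the Student form.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row data.frame `test, statistic, df, p_value, significant`.
#' @export
#' @examples
#' unpaired_t(c(1, 2, 3), c(11, 12, 13))
unpaired_t <- function(group_a, group_b, welch = FALSE, alpha = 0.05) {
  for (g in list(group_a, group_b)) {
    if (length(g) < 2 || any(!is.finite(g))) {
      stop_input("each group needs at least 2 finite values")
    }
  }
  df <- length(group_a) + length(group_b) - 2
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    stat <- if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b))
    p <- if (equal) 1 else 0
  } else {
    fit <- stats::t.test(group_a, group_b, var.equal = !welch)
    stat <- unname(fit$statistic)
    df <- unname(fit$parameter)
    p <- fit$p.value
  }
  data.frame(test = if (welch) "welch_t" else "student_t",
             statistic = stat, df = df, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA across groups (F with k - 1 and N - k
#' degrees of freedom); when the omnibus test is significant at `alpha`,
#' all pairwise Student t comparisons follow, with p-values multiplied by
#' the number of pairs (Bonferroni) and capped at 1.
#'
#' @param groups Named list: group -> numeric replicate vector; at least 2
#'   groups with at least 2 replicates each.
#' @param alpha Significance level, default 0.05.
#' @return A list:
#'   \describe{
#'     \item{anova}{One-row data.frame `statistic (F), df1, df2, p_value,
#'       significant`.}
#'     \item{pairwise}{data.frame `group_a, group_b, statistic, df,
#'       p_value, p_adjusted, significant` (NULL when the omnibus test is
#'       not significant).}
#'     \item{n_pairs}{Size of the Bonferroni family.}
#'   }
#' @export
oneway_anova_bonferroni <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_input("'groups' must be a list of at least 2 groups")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop_input("every group needs at least 2 replicates; short: ",
               paste(names(groups)[sizes < 2], collapse = ", "))
  }
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop_input("replicates must be finite")
  k <- length(groups)
  N <- sum(sizes)
  df1 <- k - 1
  df2 <- N - k
  if (stats::var(values) == 0) {
    f <- 0; p <- 1
  } else {
    lab <- factor(rep(names(groups), sizes), levels = names(groups))
    fit <- stats::anova(stats::aov(values ~ lab))
    f <- fit[["F value"]][1]
    p <- fit[["Pr(>F)"]][1]
  }
  omnibus <- data.frame(statistic = f, df1 = df1, df2 = df2, p_value = p,
                        significant = p < alpha)
  n_pairs <- choose(k, 2)
  pairwise <- NULL
  if (omnibus$significant) {
    combos <- utils::combn(names(groups), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      a <- combos[1, j]; b <- combos[2, j]
      tt <- unpaired_t(groups[[a]], groups[[b]], alpha = alpha)
      data.frame(group_a = a, group_b = b, statistic = tt$statistic,
                 df = tt$df, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
    pairwise$p_adjusted <- pmin(1, pairwise$p_value * n_pairs)
    pairwise$significant <- pairwise$p_adjusted < alpha
  }
  list(anova = omnibus, pairwise = pairwise, n_pairs = n_pairs)
}

#' Randomly subsample replicate brains per region
#'
#' Reproduces seeded random selection of a fixed number of replicate brains
#' per injected region from a replicate table.
#'
#' @param replicates data.frame with columns `region` and `brain` (plus any
#'   measurement columns).
#' @param n_per_region Number of brains to keep per region; regions with
#'   fewer brains keep all with a warning.
#' @param seed Integer seed.
#' @return The subsampled data.frame.
#' @export
subsample_brains <- function(replicates, n_per_region = 3, seed = 1L) {
  if (!all(c("region", "brain") %in% names(replicates))) {
    stop_input("'replicates' needs columns 'region' and 'brain'")
  }
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(replicates)),
                                replicates$region), function(idx) {
      brains <- unique(replicates$brain[idx])
      if (length(brains) < n_per_region) {
        warning("fewer than ", n_per_region, " brains for region ",
                replicates$region[idx[1]], "; keeping all", call. = FALSE)
        return(idx)
      }
      chosen <- sample(brains, n_per_region)
      idx[replicates$brain[idx] %in% chosen]
    }))
  })
  out <- replicates[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ipsilateral-vs-contralateral comparison from a count table
#'
#' Convenience wrapper: compares the per-(injection, source) ipsilateral
#' counts against the contralateral counts with [unpaired_t()].
#'
#' @param counts Count table.
#' @param welch,alpha Passed to [unpaired_t()].
#' @return As [unpaired_t()].
#' @export
ipsi_contra_test <- function(counts, welch = FALSE, alpha = 0.05) {
  counts <- validate_counts(counts)
  ipsi <- counts$count[counts$side == "ipsi"]
  contra <- counts$count[counts$side == "contra"]
  unpaired_t(ipsi, contra, welch = welch, alpha = alpha)
}
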