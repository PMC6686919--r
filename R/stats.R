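# Proteome-size contrasts between pathway-positive and pathway-negative
# groups: unpaired two-tailed t-tests, with Monte-Carlo utilities over the
# cohort generator's size model.

#' Unpaired two-tailed two-sample t-test
#'
#' Thin wrapper over [stats::t.test()]: `POOLED` is the classical Student
#' test (pooled variance, `df = n_x + n_y - 2`), `WELCH` the
#' Satterthwaite-df variant. Two groups with zero variance and equal means
#' return `t = 0, p = 1`.
#'
#' @param x,y Numeric vectors, each with >= 2 finite values.
#' @param variant `"POOLED"` (default) or `"WELCH"`.
#' @return One-row tibble: `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @examples
#' two_sample_t(c(4, 5, 6), c(1, 2, 3)) # t = 3/sqrt(2/3), df = 4
#' @export
two_sample_t <- function(x, y, variant = c("POOLED", "WELCH")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2 || !all(is.finite(c(x, y)))) {
    stop("each group needs >= 2 finite values", call. = FALSE)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate zero-variance groups: equal means are a null result,
    # different means an (infinitely) significant one
    equal <- mean(x) == mean(y)
    return(tibble::tibble(
      t_statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
      degrees_of_freedom = length(x) + length(y) - 2,
      p_value = if (equal) 1 else 0))
  }
  ht <- t.test(x, y, var.equal = (variant == "POOLED"),
               alternative = "two.sided")
  tibble::tibble(t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Compare proteome sizes between pathway-positive and -negative groups
#'
#' Splits the matrix rows by a pathway boolean and contrasts their proteome
#' sizes with [two_sample_t()]. For `"polyp_complete"`, the contrast is
#' complete vs absent-all (partial polyP proteomes are excluded), mirroring
#' the all-three vs none-of-three comparison.
#'
#' @param matrix A `pathway_matrix`.
#' @param pathway_id One pathway id from [pathway_definitions()].
#' @param alpha Significance level (default 0.05).
#' @param variant t-test variant, see [two_sample_t()].
#' @return A `reserve_comparison` object; see [tidy()] / [glance()].
#' @export
compare_by_pathway <- function(matrix, pathway_id, alpha = 0.05,
                               variant = c("POOLED", "WELCH")) {
  variant <- match.arg(variant)
  if (pathway_id == "polyp_complete") {
    with_sizes <- matrix$proteome_size[matrix$polyp_status == "complete"]
    without_sizes <- matrix$proteome_size[matrix$polyp_status == "absent_all"]
  } else {
    col <- paste0("pathway_", pathway_id)
    if (!col %in% names(matrix)) {
      stop("unknown pathway: ", pathway_id, call. = FALSE)
    }
    with_sizes <- matrix$proteome_size[matrix[[col]]]
    without_sizes <- matrix$proteome_size[!matrix[[col]]]
  }
  if (length(with_sizes) < 2 || length(without_sizes) < 2) {
    stop("each group needs >= 2 proteomes for pathway ", pathway_id,
         call. = FALSE)
  }
  tt <- two_sample_t(with_sizes, without_sizes, variant)
  structure(list(pathway_id = pathway_id,
                 n_with = length(with_sizes),
                 n_without = length(without_sizes),
                 mean_with = mean(with_sizes),
                 mean_without = mean(without_sizes),
                 t_statistic = tt$t_statistic,
                 degrees_of_freedom = tt$degrees_of_freedom,
                 p_value = tt$p_value,
                 alpha = alpha,
                 significant = tt$p_value < alpha,
                 variant = variant,
                 sizes_with = with_sizes,
                 sizes_without = without_sizes),
            class = "reserve_comparison")
}

#' @export
print.reserve_comparison <- function(x, ...) {
  cat(sprintf(
    "<reserve_comparison> %s: %d with (mean %.1f) vs %d without (mean %.1f)\n  %s t = %.3f, df = %.1f, p = %.3g (%ssignificant at alpha %.2g)\n",
    x$pathway_id, x$n_with, x$mean_with, x$n_without, x$mean_without,
    x$variant, x$t_statistic, x$degrees_of_freedom, x$p_value,
    if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @rdname compare_by_pathway
#' @param x A `reserve_comparison`.
#' @param ... Unused.
#' @export
tidy.reserve_comparison <- function(x, ...) {
  tibble::tibble(pathway_id = x$pathway_id, n_with = x$n_with,
                 n_without = x$n_without, mean_with = x$mean_with,
                 mean_without = x$mean_without,
                 t_statistic = x$t_statistic,
                 degrees_of_freedom = x$degrees_of_freedom,
                 p_value = x$p_value, significant = x$significant)
}

#' @rdname compare_by_pathway
#' @export
glance.reserve_comparison <- function(x, ...) {
  tibble::tibble(t_statistic = x$t_statistic,
                 degrees_of_freedom = x$degrees_of_freedom,
                 p_value = x$p_value, alpha = x$alpha, variant = x$variant)
}

#' Run the size contrast for every callable pathway
#'
#' @param matrix A `pathway_matrix`.
#' @param pathway_ids Pathways to test (default: all boolean pathway columns
#'   present); pathways whose groups are too small are skipped with a
#'   message.
#' @param alpha,variant See [compare_by_pathway()].
#' @return Tidy tibble, one row per tested pathway.
#' @export
compare_all_pathways <- function(matrix, pathway_ids = NULL, alpha = 0.05,
                                 variant = "POOLED") {
  if (is.null(pathway_ids)) {
    pathway_ids <- sub("^pathway_", "", grep("^pathway_", names(matrix),
                                             value = TRUE))
  }
  rows <- lapply(pathway_ids, function(p) {
    cmp <- tryCatch(compare_by_pathway(matrix, p, alpha, variant),
                    error = function(e) NULL)
    if (is.null(cmp)) NULL else tidy(cmp)
  })
  dplyr::bind_rows(rows)
}

#' Monte-Carlo p-values from the generator's proteome-size model
#'
#' Draws repeated two-group cohorts from the decoy-count sampler — the same
#' size model [generate_cohort()] uses — with the pathway-positive group
#' shifted by `size_effect`, and returns the t-test p-value of each
#' replicate. With `size_effect = 0` this is the null (type-I error) sweep;
#' with a planted effect it is a power sweep.
#'
#' @param n_rep Number of replicate cohorts.
#' @param n_per_group Proteomes per group.
#' @param size_effect Planted difference in mean size (proteins/proteome).
#' @param sampler [sampler_spec()] for the baseline size distribution.
#' @param variant t-test variant.
#' @param seed Integer seed.
#' @return Numeric vector of `n_rep` p-values.
#' @export
size_contrast_pvalues <- function(n_rep, n_per_group, size_effect,
                                  sampler = sampler_spec("normal", mean = 3000, sd = 300),
                                  variant = "POOLED", seed = 1L) {
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_rep), function(r) {
      a <- draw_sampler(sampler, n_per_group) + size_effect
      b <- draw_sampler(sampler, n_per_group)
      two_sample_t(a, b, variant)$p_value
    }, numeric(1))
  })
}
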