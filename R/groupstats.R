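# Randomized-block (within-subject) one-way and two-way ANOVA with Tukey
# HSD post-hoc tests and simple main effects. Each effect is tested against
# its own interaction with the block factor, the within-subject convention
# that gives df = (a-1, (a-1)(n-1)) for a levels and n blocks.

#' Complete balanced block design
#'
#' @param response Numeric response values.
#' @param block Block (subject / replicate) factor.
#' @param factorA First within-block factor (e.g. task).
#' @param factorB Optional second within-block factor (e.g. training vs
#'   test task).
#' @return Object of class \code{block_design} (a data frame). Errors if
#'   any block x level combination is not observed exactly once.
#' @export
block_design <- function(response, block, factorA, factorB = NULL) {
  d <- data.frame(response = as.numeric(response),
                  block = factor(block), A = factor(factorA))
  if (!is.null(factorB)) d$B <- factor(factorB)
  tab <- if (is.null(factorB)) table(d$block, d$A)
         else table(d$block, d$A, d$B)
  if (any(tab != 1L))
    stop("design must be complete and balanced: every block x level ",
         "combination observed exactly once", call. = FALSE)
  class(d) <- c("block_design", "data.frame")
  d
}

# Extract F, df and p for one effect from a summary.aov stratum, guarding
# the zero-variance edge cases (no treatment effect -> F = 0, p = 1).
.extract_effect <- function(stratum, effect) {
  tab <- stratum[[1]]
  rn <- trimws(rownames(tab))
  i <- match(effect, rn)
  ss_eff <- tab[i, "Sum Sq"]
  df1 <- tab[i, "Df"]
  j <- match("Residuals", rn)
  ss_err <- tab[j, "Sum Sq"]
  df2 <- tab[j, "Df"]
  ms_eff <- ss_eff / df1
  ms_err <- ss_err / df2
  if (ss_eff <= 1e-12 * max(ss_err, 1)) {
    f <- 0; p <- 1
  } else if (ms_err <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_eff / ms_err
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  data.frame(effect = effect, SS = ss_eff, df1 = df1, df2 = df2,
             MS = ms_eff, error_MS = ms_err, F = f, p = p)
}

#' Randomized-block one-way ANOVA
#'
#' Within-subject one-way ANOVA: the treatment effect is tested against the
#' block-by-treatment interaction, with df = (a-1, (a-1)(n-1)) for a levels
#' and n blocks (e.g. df = (4, 20) for 5 tasks and 6 subjects).
#'
#' @param design A \code{\link{block_design}} with one factor.
#' @return Data frame with \code{effect}, \code{SS}, \code{df1},
#'   \code{df2}, \code{MS}, \code{error_MS}, \code{F}, \code{p}.
#' @export
rb_anova1 <- function(design) {
  stopifnot(inherits(design, "block_design"))
  if (!is.null(design$B))
    stop("use rb_anova2 for a two-factor design", call. = FALSE)
  if (nlevels(design$A) < 2 || nlevels(design$block) < 2)
    stop("need >= 2 levels and >= 2 blocks", call. = FALSE)
  fit <- stats::aov(response ~ A + Error(block/A), data = design)
  s <- summary(fit)
  .extract_effect(s[["Error: block:A"]], "A")
}

#' Randomized-block two-way ANOVA
#'
#' Within-subject two-way ANOVA; each main effect and the interaction is
#' tested against its own interaction with the block factor:
#' df(A) = (a-1, (a-1)(n-1)), df(B) = (b-1, (b-1)(n-1)),
#' df(AB) = ((a-1)(b-1), (a-1)(b-1)(n-1)). For a 5 x 5 design with 6
#' blocks the interaction df is (16, 80).
#'
#' @param design A \code{\link{block_design}} with two factors.
#' @return Data frame with one row per effect ("A", "B", "A:B").
#' @export
rb_anova2 <- function(design) {
  stopifnot(inherits(design, "block_design"))
  if (is.null(design$B))
    stop("two-factor design required", call. = FALSE)
  fit <- stats::aov(response ~ A * B + Error(block/(A * B)), data = design)
  s <- summary(fit)
  rbind(.extract_effect(s[["Error: block:A"]], "A"),
        .extract_effect(s[["Error: block:B"]], "B"),
        .extract_effect(s[["Error: block:A:B"]], "A:B"))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range based adjusted p-values for all pairs of level means,
#' using the supplied error mean square and degrees of freedom (for
#' within-subject designs: the effect's own block-interaction error term).
#'
#' @param means Named numeric vector of level means.
#' @param error_MS Error mean square (> 0).
#' @param error_df Error degrees of freedom (>= 1).
#' @param n Number of observations per level mean.
#' @return Data frame with \code{level1}, \code{level2}, \code{diff},
#'   \code{q}, \code{p_adj}.
#' @export
tukey_hsd <- function(means, error_MS, error_df, n) {
  if (!is.numeric(error_MS) || error_MS <= 0)
    stop("'error_MS' must be positive", call. = FALSE)
  if (error_df < 1) stop("'error_df' must be >= 1", call. = FALSE)
  k <- length(means)
  if (is.null(names(means))) names(means) <- seq_len(k)
  se <- sqrt(error_MS / n)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    level1 = names(means)[pairs[1, ]],
    level2 = names(means)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]])
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = error_df,
                             lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey HSD for a one-way block ANOVA
#'
#' Convenience wrapper combining \code{\link{rb_anova1}} and
#' \code{\link{tukey_hsd}} on the same error term.
#'
#' @param design A one-factor \code{\link{block_design}}.
#' @return Data frame of pairwise comparisons.
#' @export
tukey_hsd_block <- function(design) {
  an <- rb_anova1(design)
  means <- tapply(design$response, design$A, mean)
  tukey_hsd(means, an$error_MS, an$df2, nlevels(design$block))
}

#' Simple main effects in a two-factor block design
#'
#' One-way randomized-block ANOVA of the non-fixed factor within each level
#' of the fixed factor; the usual follow-up to a significant interaction.
#'
#' @param design A two-factor \code{\link{block_design}}.
#' @param fix Which factor to hold fixed: "A" or "B".
#' @return Data frame with one row per level of the fixed factor.
#' @export
simple_main_effects <- function(design, fix = c("B", "A")) {
  stopifnot(inherits(design, "block_design"))
  if (is.null(design$B)) stop("two-factor design required", call. = FALSE)
  fix <- match.arg(fix)
  vary <- if (fix == "B") "A" else "B"
  out <- NULL
  for (lev in levels(design[[fix]])) {
    d <- design[design[[fix]] == lev, ]
    sub <- block_design(d$response, d$block, d[[vary]])
    an <- rb_anova1(sub)
    an$effect <- paste0(vary, " | ", fix, "=", lev)
    out <- rbind(out, an)
  }
  out
}

#' Export an ANOVA table as CSV
#'
#' @param anova_table Data frame from \code{\link{rb_anova1}} or
#'   \code{\link{rb_anova2}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_anova_csv <- function(anova_table, path) {
  utils::write.csv(anova_table, path, row.names = FALSE)
  invisible(path)
}
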