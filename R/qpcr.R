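# qPCR standard-curve quantification and validation statistics.
#
# Amounts are recovered by inverting a per-gene standard curve
# ct = slope * log10(amount) + intercept, normalized to the reference
# (housekeeping) gene, and compared across iris side and day with a
# Levene-gated t-test and two-way ANOVA.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template amount over a dilution
#' series. Amplification efficiency is `10^(-1/slope) - 1`; a slope of
#' -1/log10(2) = -3.3219 corresponds to perfect doubling (efficiency 1).
#'
#' @param log10_amount numeric vector of log10 template amounts.
#' @param ct numeric vector of observed Ct values.
#' @return A `standard_curve`: list with `slope`, `intercept`, `r_squared`,
#'   `efficiency`.
#' @export
fit_standard_curve <- function(log10_amount, ct) {
  if (length(log10_amount) != length(ct))
    stop("log10_amount and ct differ in length", call. = FALSE)
  if (length(unique(log10_amount)) < 3)
    stop("standard curve needs >= 3 distinct dilution points", call. = FALSE)
  fit <- stats::lm(ct ~ log10_amount)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-12)
    stop("degenerate standard curve: zero slope", call. = FALSE)
  sstot <- sum((ct - mean(ct))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sstot
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' Quantify a sample Ct against a standard curve
#'
#' Inverts the curve: `amount = 10^((ct - intercept) / slope)`.
#'
#' @param ct Ct value(s) of the sample.
#' @param curve a [fit_standard_curve()] result.
#' @return Template amount(s) on the scale of the standards.
#' @export
quantify_sample <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0)
    stop("invalid standard curve: slope must be negative", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Expression relative to the reference gene
#'
#' @param target_amount amount(s) of the gene of interest.
#' @param reference_amount matching amount(s) of the reference
#'   (housekeeping) gene; must be positive.
#' @return `target_amount / reference_amount`.
#' @export
relative_expression <- function(target_amount, reference_amount) {
  if (any(reference_amount <= 0))
    stop("reference amount must be positive", call. = FALSE)
  target_amount / reference_amount
}

#' Levene-gated two-sample t-test
#'
#' Classic (mean-centered) Levene's test decides the t-test variant: equal
#' variances are assumed (Student's pooled t) when the Levene p-value
#' exceeds 0.05, otherwise Welch's test is used. Both tests are two-sided.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param center `"mean"` (classic Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return List with `levene_p`, `t_p`, `variant` (`"student"` or
#'   `"welch"`), `t_statistic`.
#' @export
levene_gate_t_test <- function(group_a, group_b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  cfun <- if (center == "mean") mean else stats::median
  lev <- car::leveneTest(y, g, center = cfun)
  levene_p <- lev[["Pr(>F)"]][1]
  if (!is.finite(levene_p)) levene_p <- 1  # zero spread in both groups
  variant <- if (levene_p > 0.05) "student" else "welch"
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      t_p <- 1; t_stat <- 0
    } else {
      warning("both groups have zero variance with different means; ",
              "p-value reported as a machine-epsilon bound")
      t_p <- .Machine$double.xmin
      t_stat <- sign(mean(group_a) - mean(group_b)) * Inf
    }
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = variant == "student")
    t_p <- tt$p.value
    t_stat <- unname(tt$statistic)
  }
  list(levene_p = levene_p, t_p = t_p, variant = variant, t_statistic = t_stat)
}

#' Two-way ANOVA for a side-by-day qPCR design
#'
#' Fixed-effects decomposition of relative expression over iris side
#' (dorsal/ventral), day (4/8 post-lentectomy) and their interaction, for a
#' balanced 2x2 design with replicate measurements per cell.
#'
#' @param value numeric response (relative expression).
#' @param side factor or character, `"dorsal"`/`"ventral"`.
#' @param day factor, numeric or character day labels.
#' @return Data frame with rows `side`, `day`, `side:day` and columns `df`,
#'   `sum_sq`, `f_value`, `p_value`.
#' @export
two_way_anova <- function(value, side, day) {
  side <- factor(side)
  day <- factor(day)
  if (nlevels(side) != 2 || nlevels(day) != 2)
    stop("design must have exactly two sides and two days", call. = FALSE)
  cells <- table(side, day)
  if (length(unique(as.vector(cells))) != 1)
    stop("unbalanced design: unequal replicates per cell", call. = FALSE)
  if (cells[1] < 2)
    stop("need >= 2 replicates per cell", call. = FALSE)
  if (stats::var(value) == 0) {
    # constant response: every decomposition term is null
    return(data.frame(term = c("side", "day", "side:day"),
                      df = rep(1L, 3), sum_sq = rep(0, 3),
                      f_value = rep(0, 3), p_value = rep(1, 3),
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(value ~ side * day)
  tab <- summary(fit)[[1]]
  out <- data.frame(term = c("side", "day", "side:day"),
                    df = tab$Df[1:3],
                    sum_sq = tab$`Sum Sq`[1:3],
                    f_value = tab$`F value`[1:3],
                    p_value = tab$`Pr(>F)`[1:3],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full qPCR analysis for one or more genes
#'
#' For every gene: fit its standard curve, back-transform each replicate Ct
#' to an amount, normalize replicate-wise to the reference gene of the same
#' side/day/replicate, then test dorsal versus ventral within each day
#' (Levene-gated t-test) and run the side-by-day two-way ANOVA.
#'
#' Replicates are treated as biological (n per cell); each replicate is
#' back-transformed before averaging, rather than averaging Cts first.
#'
#' @param samples data frame with columns `gene`, `side`, `day`,
#'   `replicate`, `ct`.
#' @param standards data frame with columns `gene`, `log10_amount`, `ct`.
#' @param reference_gene name of the housekeeping gene, default `"RPL27"`.
#' @return List with `curves` (per-gene efficiencies), `expression` (per
#'   sample relative expression), `t_tests` (per gene and day) and `anova`
#'   (per gene).
#' @export
qpcr_analyze <- function(samples, standards, reference_gene = "RPL27") {
  need_s <- c("gene", "side", "day", "replicate", "ct")
  if (length(setdiff(need_s, names(samples))))
    stop("samples table missing column(s): ",
         paste(setdiff(need_s, names(samples)), collapse = ", "), call. = FALSE)
  if (length(setdiff(c("gene", "log10_amount", "ct"), names(standards))))
    stop("standards table needs gene, log10_amount, ct", call. = FALSE)
  if (!reference_gene %in% samples$gene)
    stop("reference gene ", reference_gene, " absent from samples",
         call. = FALSE)
  genes <- unique(samples$gene)
  curves <- lapply(stats::setNames(genes, genes), function(g) {
    std <- standards[standards$gene == g, ]
    if (nrow(std) == 0) stop("no standards for gene ", g, call. = FALSE)
    fit_standard_curve(std$log10_amount, std$ct)
  })
  samples$amount <- vapply(seq_len(nrow(samples)), function(i)
    quantify_sample(samples$ct[i], curves[[samples$gene[i]]]), numeric(1))
  ref <- samples[samples$gene == reference_gene, ]
  key <- function(df) paste(df$side, df$day, df$replicate)
  expr <- samples[samples$gene != reference_gene, ]
  ref_amount <- ref$amount[match(key(expr), key(ref))]
  if (anyNA(ref_amount))
    stop("missing reference-gene measurement for some side/day/replicate",
         call. = FALSE)
  expr$rel_expr <- relative_expression(expr$amount, ref_amount)

  tgenes <- setdiff(genes, reference_gene)
  t_tests <- do.call(rbind, lapply(tgenes, function(g) {
    do.call(rbind, lapply(sort(unique(expr$day)), function(dy) {
      sub <- expr[expr$gene == g & expr$day == dy, ]
      dv <- sub$rel_expr[sub$side == "dorsal"]
      vv <- sub$rel_expr[sub$side == "ventral"]
      res <- levene_gate_t_test(dv, vv)
      data.frame(gene = g, day = dy, levene_p = res$levene_p,
                 t_p = res$t_p, variant = res$variant,
                 stringsAsFactors = FALSE)
    }))
  }))
  anova_tab <- do.call(rbind, lapply(tgenes, function(g) {
    sub <- expr[expr$gene == g, ]
    res <- two_way_anova(sub$rel_expr, sub$side, sub$day)
    cbind(gene = g, res, stringsAsFactors = FALSE)
  }))
  list(curves = curves, expression = expr, t_tests = t_tests,
       anova = anova_tab)
}
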