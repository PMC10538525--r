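# Validation and genetics-support statistics: tip-count validation R^2,
# paired comparison of imaging conditions, broad-sense heritability from
# replicated genotype trials, and linkage-block-based Bonferroni
# thresholds for association scans.

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  (sxy * sxy) / (sxx * syy)
}

#' Two-sided paired t-test
#'
#' @param x,y Paired numeric vectors, length n >= 2.
#' @return List: `t`, `p` (from the t distribution with n - 1 df),
#'   `mean_diff`, and `degenerate` (TRUE when the differences have zero
#'   variance, in which case t and p are NA).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 2) stopf("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) return(list(t = 0, p = 1, mean_diff = 0, degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, mean_diff = md,
                degenerate = TRUE))
  }
  t <- md / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), mean_diff = md,
       degenerate = FALSE)
}

#' Replicated phenotype table
#'
#' @param genotype Genotype identifiers (one per observation).
#' @param value Trait values.
#' @param trait Trait name (metadata only).
#' @return An object of class `replicated_phenotypes`.
#' @export
replicated_phenotypes <- function(genotype, value, trait = "trait") {
  if (length(genotype) != length(value)) stopf("lengths differ")
  ok <- is.finite(value)
  structure(list(genotype = as.character(genotype)[ok],
                 value = as.numeric(value)[ok], trait = trait),
            class = "replicated_phenotypes")
}

#' Broad-sense heritability from replicated genotypes
#'
#' H^2 = Vg / (Vg + Ve / r), with the variance components estimated by
#' one-way random-effects ANOVA (method of moments): Ve is the
#' within-genotype mean square, Vg = (between MS - within MS) / r,
#' truncated at zero, and r is the number of replicates per genotype
#' (harmonic-style ANOVA coefficient for unbalanced data, flagged in the
#' output).
#'
#' @param ph A [replicated_phenotypes()] object.
#' @return List: `H2` in [0, 1], `Vg`, `Ve`, `r`, `balanced`.
#' @export
heritability <- function(ph) {
  stopifnot(inherits(ph, "replicated_phenotypes"))
  g <- factor(ph$genotype)
  y <- ph$value
  G <- nlevels(g)
  if (G < 2) stopf("need at least 2 genotypes")
  ng <- tabulate(g)
  N <- length(y)
  if (!any(ng >= 2)) stopf("need replication (some genotype with >= 2 reps)")
  means <- tapply(y, g, mean)
  ss_within <- sum((y - means[g])^2)
  df_within <- N - G
  ss_between <- sum(ng * (means - mean(y))^2)
  df_between <- G - 1
  ms_within <- if (df_within > 0) ss_within / df_within else 0
  ms_between <- ss_between / df_between
  # ANOVA coefficient for the group-size weighting; equals r when balanced
  r0 <- (N - sum(ng^2) / N) / (G - 1)
  Vg <- max(0, (ms_between - ms_within) / r0)
  Ve <- ms_within
  H2 <- if (Vg + Ve / r0 > 0) Vg / (Vg + Ve / r0) else 0
  list(H2 = H2, Vg = Vg, Ve = Ve, r = r0,
       balanced = length(unique(ng)) == 1)
}

#' Tip-count validation
#'
#' Compares ground-truth (or manually counted) root tip numbers with
#' tip counts measured on cleaned and on raw (uncleaned) masks of the
#' same images. The point of the design: debris inflates raw counts by a
#' *variable* amount per image, which is what degrades the uncleaned
#' correlation -- a constant offset would leave R^2 unchanged.
#'
#' @param truth,cleaned,raw Aligned count vectors, n >= 10.
#' @return An object of class `validation_result`: `r2_cleaned`,
#'   `r2_uncleaned`, `n`, and the per-image `table`.
#' @export
tip_validation <- function(truth, cleaned, raw) {
  n <- length(truth)
  if (length(cleaned) != n || length(raw) != n) stopf("unaligned vectors")
  if (n < 10) stopf("need at least 10 images")
  res <- list(r2_cleaned = r_squared(truth, cleaned),
              r2_uncleaned = r_squared(truth, raw),
              n = n,
              table = data.frame(truth = truth, cleaned = cleaned,
                                 raw = raw))
  structure(res, class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> n=%d  R2 cleaned=%.3f  uncleaned=%.3f\n",
              x$n, x$r2_cleaned, x$r2_uncleaned))
  invisible(x)
}

#' Count linkage blocks by greedy window clumping
#'
#' Left-to-right scan per chromosome: the first unassigned SNP seeds a
#' block; each subsequent SNP joins the current block iff it lies within
#' `window_bp` of the seed AND its squared genotype correlation with the
#' seed is at least `r2_min`; otherwise it seeds a new block. This is a
#' seed-based approximation of LD clumping, not a reimplementation of
#' Plink; block counts on real data will differ from published values.
#'
#' @param positions Sorted SNP positions in bp.
#' @param dosages SNP x line matrix of biallelic dosages (0/1/2, NA
#'   allowed), rows aligned with `positions`.
#' @param chromosome Optional chromosome id per SNP.
#' @param window_bp Window width from the block seed.
#' @param r2_min Minimum squared correlation with the seed.
#' @return Total number of blocks B.
#' @export
count_linkage_blocks <- function(positions, dosages, chromosome = NULL,
                                 window_bp = 200000, r2_min = 0.2) {
  n <- length(positions)
  if (n < 1) stopf("need at least one SNP")
  if (is.null(chromosome)) chromosome <- rep(1L, n)
  if (nrow(dosages) != n) stopf("dosages rows must match positions")
  B <- 0L
  for (chr in unique(chromosome)) {
    i <- which(chromosome == chr)
    pos <- positions[i]
    if (is.unsorted(pos)) stopf("positions must be sorted within chromosome")
    dos <- dosages[i, , drop = FALSE]
    seed <- NA_integer_
    for (k in seq_along(pos)) {
      new_block <- TRUE
      if (!is.na(seed) && pos[k] - pos[seed] <= window_bp) {
        a <- dos[seed, ]; b <- dos[k, ]
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) >= 2 && sd(a[ok]) > 0 && sd(b[ok]) > 0) {
          r2 <- cor(a[ok], b[ok])^2
          if (r2 >= r2_min) new_block <- FALSE
        }
      }
      if (new_block) { B <- B + 1L; seed <- k }
    }
  }
  B
}

#' Linkage-block Bonferroni threshold
#'
#' Treating each linkage block as one independent test, the genome-wide
#' significance threshold on the -log10 scale is -log10(alpha / B).
#'
#' @param alpha Significance level in (0, 1).
#' @param B Number of linkage blocks (>= 1).
#' @return -log10(alpha / B).
#' @export
bonferroni_block_threshold <- function(alpha, B) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  if (B < 1 || B != round(B)) stopf("B must be a positive integer")
  -log10(alpha / B)
}

#' Read a replicated phenotype CSV
#'
#' Expected columns: `genotype`, `replicate`, then one column per trait.
#'
#' @param path CSV path.
#' @param trait Trait column to extract.
#' @return A [replicated_phenotypes()] object.
#' @export
read_phenotypes_csv <- function(path, trait) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!trait %in% names(df)) stopf("trait column '%s' not found", trait)
  replicated_phenotypes(df$genotype, df[[trait]], trait)
}

#' Read a genotype dosage CSV
#'
#' Expected columns: `chrom`, `pos`, then one 0/1/2 dosage column per
#' line.
#'
#' @param path CSV path.
#' @return List: `chromosome`, `positions`, `dosages` matrix.
#' @export
read_genotypes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stopf("genotype CSV needs 'chrom' and 'pos' columns")
  dos <- as.matrix(df[, setdiff(names(df), c("chrom", "pos")), drop = FALSE])
  if (length(dos) && !all(dos[is.finite(dos)] %in% 0:2))
    stopf("dosages must be 0, 1, 2 or missing")
  list(chromosome = df$chrom, positions = df$pos, dosages = dos)
}
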