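#' Count codons in a coding sequence
#'
#' @param cds A `coding_sequence` from [validate_cds()].
#' @return Object of class `codon_counts`: list with `id`, `counts` (named
#'   integer vector over all 64 codons), `n` (total sense codon count; stop
#'   codons are excluded, none exist by construction) and `code`.
#' @export
count_codons <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (length(cds$codons) == 0) stop("no codons in sequence '", cds$id, "'")
  counts <- table(factor(cds$codons, levels = all_codons()))
  counts <- stats::setNames(as.integer(counts), all_codons())
  structure(list(id = cds$id, counts = counts,
                 n = sum(counts[cds$code$sense]), code = cds$code),
            class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count times the family degeneracy,
#' divided by the family total: the ratio of observed to expected usage
#' under uniform synonymous choice. Codons of families never observed in
#' the gene are `NA`, never 0. Observed one-fold families have RSCU 1.
#'
#' @param counts A `codon_counts` object.
#' @return Named numeric vector over the sense codons of the bound code.
#' @export
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- counts$code
  out <- stats::setNames(rep(NA_real_, length(code$sense)), code$sense)
  for (fam in code$families) {
    tot <- sum(counts$counts[fam])
    if (tot > 0) out[fam] <- counts$counts[fam] * length(fam) / tot
  }
  out
}

#' GC content at synonymous third positions (GC3s)
#'
#' G+C fraction at third codon positions, restricted to codons belonging to
#' synonymous families with degeneracy >= 2 (one-fold codons such as
#' ATG/TGG under the standard code carry no synonymous signal). `NA` when
#' the gene has no such codons.
#'
#' @param counts A `codon_counts` object.
#' @return Fraction in \[0, 1\], or `NA`.
#' @export
gc3s <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- counts$code
  syn <- code$sense[code$degeneracy[code$sense] >= 2]
  n <- sum(counts$counts[syn])
  if (n == 0) return(NA_real_)
  gc <- syn[substr(syn, 3, 3) %in% c("G", "C")]
  sum(counts$counts[gc]) / n
}

# GC12 (mean of first- and second-position GC) and GC3 (third-position GC)
# over ALL codons -- the neutrality-plot axes, distinct from GC3s.
gc_positions <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  sense <- counts$code$sense
  cts <- counts$counts[sense]
  n <- sum(cts)
  if (n == 0) return(c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_))
  posgc <- function(p) {
    sum(cts[substr(sense, p, p) %in% c("G", "C")]) / n
  }
  c(gc1 = posgc(1), gc2 = posgc(2), gc3 = posgc(3))
}

#' Wright's effective number of codons (ENc)
#'
#' Wright's (1990) estimator with CodonW-compatible conventions. Per
#' synonymous family with at least 2 observed codons the homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; per degeneracy class the mean
#' `F` over families with a defined value is taken; the estimate is the
#' sum over classes of (number of families in the class under the code)
#' divided by the class mean, with one-fold families contributing their
#' count. A missing three-fold class (isoleucine unobserved) is imputed as
#' the mean of the two- and four-fold class means; if any other class has
#' no defined mean (or a zero mean) the estimate is `NA`. The result is
#' capped at the number of sense codons (61 under table 1, 63 under
#' table 6). Genes shorter than 30 codons are flagged with a warning.
#'
#' @param counts A `codon_counts` object.
#' @return ENc value (between 20 and the sense-codon count for table 1),
#'   or `NA`.
#' @export
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- counts$code
  if (counts$n < 30) {
    warning(sprintf("gene '%s' has only %d codons; ENc is unstable below 30",
                    counts$id, counts$n))
  }
  deg <- lengths(code$families)
  fam_F <- vapply(code$families, function(fam) {
    n <- sum(counts$counts[fam])
    if (n < 2) return(NA_real_)
    p <- counts$counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classes <- sort(unique(deg[deg >= 2]))
  fbar <- vapply(classes, function(k) {
    f <- fam_F[deg == k]
    if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
  }, numeric(1))
  names(fbar) <- classes
  # impute a missing three-fold class from its neighbours
  if ("3" %in% names(fbar) && is.na(fbar[["3"]]) &&
      !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (anyNA(fbar) || any(fbar <= 0)) return(NA_real_)
  contrib <- vapply(seq_along(classes), function(i) {
    sum(deg == classes[i]) / fbar[i]
  }, numeric(1))
  val <- sum(deg == 1) + sum(contrib)
  min(val, length(code$sense))
}

#' Expected ENc under mutation pressure alone
#'
#' Wright's expected curve for the ENc-GC3s plot: the ENc a gene would show
#' if codon usage were driven only by the genome's third-position GC
#' content `s`, with no selection: `2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param s GC3s fraction(s) in \[0, 1\].
#' @return Expected ENc value(s).
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(s) {
  if (any(is.na(s)) || any(s < 0 | s > 1)) {
    stop("GC3s must be within [0, 1]")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Parity rule 2 point
#'
#' Third-position nucleotide bias at fourfold-degenerate sites, pooled over
#' the complete synonymous quartets of the code (codon boxes whose four
#' third-position variants all encode the same amino acid, including the
#' quartets inside six-fold families). Under mutation pressure alone
#' (Sueoka's parity rule 2) A = T and G = C at these sites, placing genes
#' at (0.5, 0.5); deviations expose strand-specific selection.
#'
#' @param counts A `codon_counts` object.
#' @return Named numeric: `at_bias` = A3/(A3+T3), `gc_bias` = G3/(G3+C3);
#'   `NA` where the denominator is 0.
#' @export
pr2 <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  cods <- unlist(counts$code$fourfold_boxes, use.names = FALSE)
  if (length(cods) == 0 || sum(counts$counts[cods]) == 0) {
    return(c(at_bias = NA_real_, gc_bias = NA_real_))
  }
  third <- substr(cods, 3, 3)
  nt <- vapply(c("A", "T", "G", "C"), function(b) {
    sum(counts$counts[cods[third == b]])
  }, numeric(1))
  at <- if (nt["A"] + nt["T"] > 0) nt["A"] / (nt["A"] + nt["T"]) else NA_real_
  gc <- if (nt["G"] + nt["C"] > 0) nt["G"] / (nt["G"] + nt["C"]) else NA_real_
  c(at_bias = unname(at), gc_bias = unname(gc))
}

#' Per-gene codon usage statistics
#'
#' Computes the full per-gene codon-usage panel for a set of coding
#' sequences: sense codon count, GC3s, GC12, GC3, ENc and the expected ENc
#' at the gene's GC3s, plus PR2 biases.
#'
#' @param cds_list List of `coding_sequence` objects.
#' @param warn_short Warn for genes under 30 codons (default TRUE).
#' @return Data frame, one row per gene.
#' @export
cub_stats <- function(cds_list, warn_short = TRUE) {
  rows <- lapply(cds_list, function(cds) {
    ct <- count_codons(cds)
    gcp <- gc_positions(ct)
    s <- gc3s(ct)
    e <- if (warn_short) enc(ct) else suppressWarnings(enc(ct))
    p <- pr2(ct)
    data.frame(id = ct$id, n_codons = ct$n, gc3s = s,
               gc12 = (gcp[["gc1"]] + gcp[["gc2"]]) / 2, gc3 = gcp[["gc3"]],
               enc = e,
               enc_expected = if (is.na(s)) NA_real_ else enc_expected(s),
               pr2_at = p[["at_bias"]], pr2_gc = p[["gc_bias"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neutrality plot regression
#'
#' Ordinary least squares of GC12 on GC3 across genes, with the Pearson
#' correlation. A slope near 1 indicates mutation pressure acting on all
#' codon positions alike; a slope near 0 indicates selection constraining
#' first and second positions.
#'
#' @param stats Data frame with columns `gc12` and `gc3` (e.g. from
#'   [cub_stats()]).
#' @return Object of class `neutrality_fit`: list with `slope`,
#'   `intercept`, `r`, `n`.
#' @export
neutrality_fit <- function(stats) {
  ok <- stats::complete.cases(stats[, c("gc12", "gc3")])
  d <- stats[ok, ]
  if (nrow(d) < 3) stop("need at least 3 genes with defined GC12 and GC3")
  if (stats::var(d$gc3) == 0) stop("zero variance in GC3")
  fit <- stats::lm(gc12 ~ gc3, data = d)
  r <- if (stats::var(d$gc12) == 0) NA_real_ else stats::cor(d$gc3, d$gc12)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, n = nrow(d)),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "<neutrality_fit> GC12 = %.4f + %.4f * GC3 (r = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r, x$n))
  invisible(x)
}

#' Principal component analysis of RSCU profiles
#'
#' Covariance-scaled PCA of per-gene RSCU vectors over the informative
#' codons (families with degeneracy >= 2). `NA` entries (unobserved
#' families) are imputed with the column mean of the observed values; the
#' imputation count is reported. Component signs are fixed so that each
#' loading vector's largest-magnitude entry is positive.
#'
#' @param rscu_list Named list (or matrix, genes x codons) of RSCU vectors
#'   as returned by [rscu()].
#' @param code A [genetic_code()] object (needed when a bare matrix is
#'   passed; otherwise taken from the column set).
#' @return Object of class `rscu_pca`: list with `scores` (genes x
#'   components), `loadings` (codons x components), `variance_fraction`,
#'   `imputed` (count of imputed cells).
#' @export
rscu_pca <- function(rscu_list, code = NULL) {
  if (is.list(rscu_list)) {
    m <- do.call(rbind, rscu_list)
    if (!is.null(names(rscu_list))) rownames(m) <- names(rscu_list)
  } else {
    m <- as.matrix(rscu_list)
  }
  if (nrow(m) < 2) stop("need at least 2 genes for PCA")
  if (!is.null(code)) {
    keep <- intersect(colnames(m),
                      code$sense[code$degeneracy[code$sense] >= 2])
    m <- m[, keep, drop = FALSE]
  }
  imputed <- sum(is.na(m))
  if (imputed > 0) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) {
        fill <- if (all(nas)) 0 else mean(m[!nas, j])
        m[nas, j] <- fill
      }
    }
    message("rscu_pca: imputed ", imputed,
            " missing RSCU cell(s) with column means")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf, center = pc$center,
                 imputed = imputed),
            class = "rscu_pca")
}

#' Parametric HGT screen from codon usage
#'
#' Compares the codon usage of a candidate gene family against its host
#' genome background, the parametric test for horizontal gene transfer: a
#' horizontally acquired family is expected to carry the donor genome's
#' compositional signature (shifted GC3s, deviant ENc, displaced RSCU
#' profile), while a family born by duplication simply reflects the host's
#' codon usage. The screen reports the ENc-GC3s table with expected-curve
#' values, PR2 points, the neutrality regression over the background, PCA
#' scores with family genes flagged, and two-sample Wilcoxon rank-sum
#' tests (family vs background) on ENc and GC3s, raw and
#' Benjamini-Hochberg adjusted. The verdict is descriptive, never causal:
#' `"CUB outlier"` when the smallest adjusted p-value is below 0.01, else
#' `"consistent with host genome codon usage"`.
#'
#' @param family_genes,background_genes Lists of `coding_sequence`
#'   objects; both must be non-empty.
#' @return Object of class `hgt_screen`: list with `stats` (per-gene table
#'   with a `set` column), `neutrality` (background fit, or NULL if the
#'   background is degenerate), `pca`, `tests` (data frame with statistic,
#'   raw and adjusted p per measure), `p_value` (headline: min adjusted),
#'   `verdict`.
#' @export
hgt_screen <- function(family_genes, background_genes) {
  if (length(family_genes) == 0) stop("family gene set is empty")
  if (length(background_genes) == 0) stop("background gene set is empty")
  fam <- cub_stats(family_genes, warn_short = FALSE)
  bg <- cub_stats(background_genes, warn_short = FALSE)
  fam$set <- "family"
  bg$set <- "background"
  stats_all <- rbind(fam, bg)
  neut <- tryCatch(neutrality_fit(bg), error = function(e) NULL)
  rscus <- c(lapply(family_genes, function(x) rscu(count_codons(x))),
             lapply(background_genes, function(x) rscu(count_codons(x))))
  names(rscus) <- stats_all$id
  code <- family_genes[[1]]$code
  pca <- rscu_pca(rscus, code = code)
  one_test <- function(measure) {
    x <- fam[[measure]]; y <- bg[[measure]]
    if (all(is.na(x)) || all(is.na(y))) {
      return(data.frame(measure = measure, statistic = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(measure = measure, statistic = unname(wt$statistic),
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  }
  tests <- rbind(one_test("enc"), one_test("gc3s"))
  tests$p_adj <- stats::p.adjust(tests$p_raw, method = "BH")
  headline <- suppressWarnings(min(tests$p_adj, na.rm = TRUE))
  if (!is.finite(headline)) headline <- NA_real_
  verdict <- if (!is.na(headline) && headline < 0.01) {
    "CUB outlier"
  } else {
    "consistent with host genome codon usage"
  }
  structure(list(stats = stats_all, neutrality = neut, pca = pca,
                 tests = tests, p_value = headline, verdict = verdict),
            class = "hgt_screen")
}

#' @export
print.hgt_screen <- function(x, ...) {
  n_f <- sum(x$stats$set == "family")
  n_b <- sum(x$stats$set == "background")
  cat(sprintf("<hgt_screen> %d family vs %d background genes\n", n_f, n_b))
  print(x$tests, row.names = FALSE)
  cat(sprintf("headline adjusted p = %.4g -> %s\n", x$p_value, x$verdict))
  invisible(x)
}
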