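gc1 <- genetic_code(1)
gc6 <- genetic_code(6)

test_that("codon counting is exact and n counts sense codons", {
  ct <- count_codons(validate_cds("ATGTTTTTC", gc1))
  expect_equal(unname(ct$counts[c("ATG", "TTT", "TTC")]), c(1L, 1L, 1L))
  expect_equal(sum(ct$counts), 3L)
  expect_equal(ct$n, 3L)

  expect_error(validate_cds("TAA", gc1), "no codons")

  withr::local_seed(3)
  for (rep in 1:5) {
    n <- sample(5:80, 1)
    cds <- make_cds(random_sense_codons(n, gc1), gc1)
    expect_equal(count_codons(cds)$n, n)
  }
})

test_that("RSCU follows its definition and NA policy", {
  cds <- make_cds(c(rep("TTT", 3), "TTC"), gc1)
  r <- rscu(count_codons(cds))
  expect_equal(unname(r[c("TTT", "TTC")]), c(1.5, 0.5))
  # unobserved family: NA, never 0
  expect_true(all(is.na(r[c("TGT", "TGC")])))

  leu <- gc1$families[["L"]]
  r2 <- rscu(count_codons(make_cds(rep(leu, 2), gc1)))
  expect_equal(unname(r2[leu]), rep(1, 6))

  # sum over each observed family equals its degeneracy
  withr::local_seed(19)
  for (rep in 1:5) {
    cds <- make_cds(random_sense_codons(200, gc6), gc6)
    r3 <- rscu(count_codons(cds))
    for (fam in gc6$families) {
      if (all(!is.na(r3[fam]))) {
        expect_equal(sum(r3[fam]), length(fam), tolerance = 1e-9)
      }
    }
  }
})

test_that("GC3s counts synonymous third positions only", {
  ct <- count_codons(make_cds(c("TTT", "TTT", "TTC", "TTC"), gc1))
  expect_equal(gc3s(ct), 0.5)
  # one-fold codons carry no signal
  expect_true(is.na(gc3s(count_codons(make_cds(c("ATG", "TGG"), gc1)))))

  # brute-force per-codon classification oracle
  withr::local_seed(29)
  for (code in list(gc1, gc6)) {
    for (rep in 1:4) {
      cods <- random_sense_codons(150, code)
      ct2 <- count_codons(make_cds(cods, code))
      syn <- cods[lengths(code$families)[code$codon_to_aa[cods]] >= 2]
      want <- mean(substr(syn, 3, 3) %in% c("G", "C"))
      expect_equal(gc3s(ct2), want)
    }
  }
})

test_that("ENc hits its analytic limits and conventions", {
  # maximal bias: one codon per amino acid
  one_per_aa <- unlist(lapply(gc1$families, function(f) rep(f[1], 3)))
  expect_equal(suppressWarnings(enc(count_codons(make_cds(one_per_aa, gc1)))),
               20)

  # uniform usage: uncapped class formula gives 2 + sum(k_class/Fbar) with
  # Fbar_k = 99/(100k - 1), i.e. 61.41...; the cap brings it to 61
  uni <- rep(gc1$sense, each = 100)
  fbar <- function(k) 99 / (100 * k - 1)
  uncapped <- 2 + 9 / fbar(2) + 1 / fbar(3) + 5 / fbar(4) + 3 / fbar(6)
  expect_gt(uncapped, 61)
  expect_equal(enc(count_codons(make_cds(uni, gc1))), 61)
  expect_equal(enc(count_codons(make_cds(rep(gc6$sense, each = 100), gc6))),
               63)

  expect_warning(enc(count_codons(make_cds(c("TTT", "TTC", "GGA"), gc1))),
                 "below 30")

  # invariant under codon relabeling within a family preserving the
  # count multiset
  base <- c(rep("GGA", 5), rep("GGC", 2), rep("GGT", 1), rep("TTT", 20),
            rep("CAA", 10), rep("CAG", 3), rep("ATT", 4), rep("ATC", 2),
            rep("CTA", 6), rep("CTC", 3))
  swapped <- c(rep("GGC", 5), rep("GGA", 2), rep("GGT", 1), rep("TTT", 20),
               rep("CAG", 10), rep("CAA", 3), rep("ATC", 4), rep("ATT", 2),
               rep("CTC", 6), rep("CTA", 3))
  expect_equal(suppressWarnings(enc(count_codons(make_cds(base, gc1)))),
               suppressWarnings(enc(count_codons(make_cds(swapped, gc1)))))
})

test_that("the expected-ENc curve matches Wright's closed form", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "within")
})

test_that("PR2 pools fourfold-degenerate third positions", {
  quart <- gc1$fourfold_boxes[["GG"]]  # glycine GGN
  p <- pr2(count_codons(make_cds(rep(quart, 3), gc1)))
  expect_equal(unname(p), c(0.5, 0.5))

  pA <- pr2(count_codons(make_cds(rep("GGA", 10), gc1)))
  expect_equal(unname(pA["at_bias"]), 1)

  # no fourfold-family codons: both NA
  pNA <- pr2(count_codons(make_cds(c("ATG", "TTT", "CAA"), gc1)))
  expect_true(all(is.na(pNA)))
})

test_that("neutrality regression matches closed-form OLS", {
  mk <- function(gc12, gc3) data.frame(gc12 = gc12, gc3 = gc3)
  eq <- neutrality_fit(mk(c(.2, .3, .4, .5), c(.2, .3, .4, .5)))
  expect_equal(eq$slope, 1)
  expect_equal(eq$r, 1)

  flat <- neutrality_fit(mk(rep(.4, 4), c(.1, .2, .3, .4)))
  expect_equal(flat$slope, 0)

  # 5-point hand-computed check
  x <- c(0.10, 0.25, 0.40, 0.55, 0.70)
  y <- c(0.30, 0.33, 0.41, 0.46, 0.52)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  fit <- neutrality_fit(mk(y, x))
  expect_equal(fit$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - sxy / sxx * mean(x),
               tolerance = 1e-12)
  expect_equal(fit$r, sxy / sqrt(sxx * sum((y - mean(y))^2)),
               tolerance = 1e-12)

  expect_error(neutrality_fit(mk(c(.1, .2), c(.1, .2))), "at least 3")
  expect_error(neutrality_fit(mk(c(.1, .2, .3), rep(.4, 3))),
               "zero variance")
})

test_that("RSCU PCA has the stated algebraic properties", {
  withr::local_seed(37)
  genes <- lapply(1:8, function(i) {
    make_cds(random_sense_codons(300, gc1), gc1, id = paste0("g", i))
  })
  rs <- lapply(genes, function(g) rscu(count_codons(g)))
  names(rs) <- paste0("g", 1:8)
  # duplicate a gene row
  rs$dup <- rs$g1
  p <- suppressMessages(rscu_pca(rs, code = gc1))
  expect_equal(unname(p$scores["dup", ]), unname(p$scores["g1", ]),
               tolerance = 1e-10)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(p$variance_fraction >= 0))

  # scores x loadings reconstruct the centered matrix
  m <- do.call(rbind, rs)
  keep <- gc1$sense[gc1$degeneracy[gc1$sense] >= 2]
  m <- m[, keep]
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- if (all(nas)) 0 else mean(m[!nas, j])
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)

  expect_error(rscu_pca(rs[1]), "at least 2")
})

test_that("hgt_screen validates inputs and reports all components", {
  withr::local_seed(43)
  bg <- sample_biased_genome(20, 120, 0.3, seed = 1, prefix = "bg")
  fam <- sample_biased_genome(4, 120, 0.3, seed = 2, prefix = "fam")
  expect_error(hgt_screen(list(), bg), "family gene set is empty")
  expect_error(hgt_screen(fam, list()), "background gene set is empty")

  scr <- suppressMessages(hgt_screen(fam, bg))
  expect_s3_class(scr, "hgt_screen")
  expect_equal(sum(scr$stats$set == "family"), 4)
  expect_equal(nrow(scr$tests), 2)
  expect_true(all(scr$tests$p_adj >= scr$tests$p_raw - 1e-12))
  expect_true(scr$verdict %in%
                c("CUB outlier", "consistent with host genome codon usage"))
})
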