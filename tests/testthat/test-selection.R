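gc1 <- genetic_code(1)
gc6 <- genetic_code(6)

test_that("NG86 site fractions match direct enumeration", {
  expect_equal(ng86_sites("ATG", gc1), c(s = 0, n = 3))
  expect_equal(ng86_sites("TTT", gc1), c(s = 1 / 3, n = 8 / 3))
  expect_error(ng86_sites("TAA", gc1), "not a sense codon")

  # exhaustive oracle over every sense codon, both tables
  for (code in list(gc1, gc6)) {
    for (cod in code$sense) {
      got <- ng86_sites(cod, code)
      want <- oracle_ng86_sites(cod, code$codon_to_aa)
      expect_equal(got, want, info = paste("table", code$table_id, cod))
      expect_gt(sum(got), 0)
      expect_lte(sum(got), 3)
    }
  }
})

test_that("pairwise NG86 handles the documented edge cases", {
  a <- make_cds(c("TTT", "GGC", "GGC", "GGC"), gc1, "a")
  b <- make_cds(c("TTC", "GGC", "GGC", "GGC"), gc1, "b")
  r <- ng86_pair(a, b)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)
  expect_true(is.na(r$omega) || r$omega == 0)  # dN = 0 -> omega 0

  ident <- ng86_pair(a, a)
  expect_equal(ident$Sd, 0)
  expect_equal(ident$Nd, 0)
  expect_equal(ident$dS, 0)
  expect_equal(ident$dN, 0)
  expect_true(is.na(ident$omega))

  expect_error(ng86_pair(make_cds("TTT", gc1), make_cds(c("TTT", "TTC"), gc1)),
               "differ in codon length")
  # a lone synonymous difference saturates the correction: spec error path
  expect_error(ng86_pair(make_cds("TTT", gc1), make_cds("TTC", gc1)),
               "correction undefined for dS")
})

test_that("NG86 difference counts match the pathway oracle", {
  withr::local_seed(47)
  for (code in list(gc1, gc6)) {
    for (rep in 1:10) {
      a <- random_sense_codons(50, code)
      # moderate divergence so the JC correction stays defined
      b <- a
      mut <- runif(50) < 0.3
      b[mut] <- random_sense_codons(sum(mut), code)
      got <- tryCatch(ng86_pair(a, b, code = code),
                      error = function(e) e)
      want <- oracle_ng86_pair(a, b, code$codon_to_aa)
      if (inherits(got, "error")) {
        expect_true(is.na(want$dS) || is.na(want$dN))
        next
      }
      expect_equal(got$S, want$S, tolerance = 1e-12)
      expect_equal(got$N, want$N, tolerance = 1e-12)
      expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
      expect_equal(got$dS, want$dS, tolerance = 1e-10)
      expect_equal(got$dN, want$dN, tolerance = 1e-10)
      expect_equal(got$codons_skipped, want$skipped)
    }
  }
})

test_that("NG86 estimates are symmetric in their arguments", {
  withr::local_seed(53)
  for (rep in 1:5) {
    a <- random_sense_codons(60, gc1)
    b <- a
    mut <- runif(60) < 0.25
    b[mut] <- random_sense_codons(sum(mut), gc1)
    r1 <- tryCatch(ng86_pair(a, b, code = gc1), error = function(e) NULL)
    if (is.null(r1)) next
    r2 <- ng86_pair(b, a, code = gc1)
    expect_equal(r1$S, r2$S)
    expect_equal(r1$Sd, r2$Sd)
    expect_equal(r1$omega, r2$omega)
  }
})

test_that("fitch reconstruction follows the deterministic tie-break rules", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  m <- rbind(a = "TTT", b = "TTT", c = "TTC")
  rec <- fitch_ancestral(tr, m, gc1)
  expect_equal(rec$changes, 1)
  # root set is {TTC,TTT}; lexicographic rule assigns TTC to the root,
  # and the (a,b) ancestor keeps TTT
  expect_equal(unname(rec$codons["N1", 1]), "TTC")
  expect_equal(unname(rec$codons["N2", 1]), "TTT")

  # all tips identical: all ancestors identical, 0 changes
  m2 <- rbind(a = c("ATG", "CAA"), b = c("ATG", "CAA"), c = c("ATG", "CAA"))
  rec2 <- fitch_ancestral(tr, m2, gc1)
  expect_equal(rec2$changes, 0)
  expect_true(all(rec2$codons == rep(c("ATG", "CAA"), each = 5)))

  expect_error(fitch_ancestral(tr, rbind(a = "TTT", b = "TTT"), gc1),
               "absent from alignment")

  # gapped column dropped with a message
  m3 <- rbind(a = c("TTT", "---"), b = c("TTT", "AAA"), c = c("TTC", "AAA"))
  expect_message(rec3 <- fitch_ancestral(tr, m3, gc1), "dropped 1")
  expect_equal(ncol(rec3$codons), 1)
})

test_that("fitch change counts equal the exhaustive parsimony minimum", {
  withr::local_seed(59)
  states <- c("TTT", "TTC", "TTA")
  for (rep in 1:8) {
    n_tip <- sample(3:5, 1)
    tr <- ape::rtree(n_tip, tip.label = letters[1:n_tip])
    n_col <- sample(1:3, 1)
    m <- matrix(sample(states, n_tip * n_col, replace = TRUE), n_tip,
                dimnames = list(letters[1:n_tip], NULL))
    rec <- fitch_ancestral(tr, m, gc1)
    want <- sum(vapply(seq_len(n_col), function(j) {
      oracle_fitch_length(tr, stats::setNames(m[, j], rownames(m)))
    }, numeric(1)))
    expect_equal(rec$changes, want)
    # the returned labeling itself achieves the minimum
    tr_l <- fadevo:::label_phylo(tr)
    labs <- fadevo:::node_labels(tr_l)
    realized <- sum(rec$codons[labs[tr$edge[, 1]], , drop = FALSE] !=
                      rec$codons[labs[tr$edge[, 2]], , drop = FALSE])
    expect_equal(realized, want)
  }
})

test_that("branch omegas behave on degenerate and two-taxon trees", {
  # star-ish tree with identical tips: no changes anywhere
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  m <- matrix(rep(random_sense_codons(40, gc1), each = 4), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  withr::local_seed(61)
  m[] <- rep(random_sense_codons(40, gc1), each = 4)
  bo <- branch_omega(tr, m, gc1)
  expect_true(all(bo$branches$Sd == 0 & bo$branches$Nd == 0))
  expect_true(all(is.na(bo$branches$omega)))

  # two-taxon tree: the root is one of the two observed codons per column,
  # so pooling both branches recovers the tip-pair difference counts
  # exactly; site counts are summed over the two branches (about twice the
  # pairwise sites), which leaves omega equal up to the curvature of the
  # Jukes-Cantor correction -- negligible at low divergence
  tr2 <- ape::read.tree(text = "(x:0.1,y:0.1);")
  a <- random_sense_codons(400, gc1)
  b <- a
  mut <- runif(400) < 0.05
  b[mut] <- random_sense_codons(sum(mut), gc1)
  m2 <- rbind(x = a, y = b)
  bo2 <- branch_omega(tr2, m2, gc1, clades = list(all = c("x", "y")))
  direct <- ng86_pair(a, b, code = gc1)
  pooled <- bo2$clades[bo2$clades$clade == "all", ]
  expect_equal(pooled$Sd, direct$Sd, tolerance = 1e-9)
  expect_equal(pooled$Nd, direct$Nd, tolerance = 1e-9)
  expect_equal(pooled$S + pooled$N, 2 * (direct$S + direct$N),
               tolerance = 1e-9)
  expect_equal(pooled$omega, direct$omega, tolerance = 0.1)
})
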