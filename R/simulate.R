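#' GY94-style codon substitution model
#'
#' Mechanistic codon model with a transition/transversion ratio `kappa`,
#' stationary sense-codon frequencies `pi` and a nonsynonymous/synonymous
#' rate ratio `omega`, optionally overridden per branch. Default
#' frequencies are F1x4 built from a GC content: each position draws G and
#' C with probability `gc/2` each and A and T with `(1 - gc)/2` each, stop
#' codons removed and the vector renormalized, so one knob realizes both
#' AT-rich *Tetrahymena*-like backgrounds and GC-shifted "alien" pools.
#' Defaults are the package's neutral stated world: `kappa = 1` (no
#' transition bias, the regime where the NG86 counting estimator is
#' consistent) and `gc = 0.5` (uniform codon frequencies).
#'
#' @param code A [genetic_code()] object.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Default dN/dS rate ratio (>= 0).
#' @param pi Stationary frequencies over the code's sense codons (named or
#'   in `code$sense` order, summing to 1), or `NULL` to build F1x4
#'   frequencies from `gc`.
#' @param gc GC content for the F1x4 default frequencies.
#' @param omega_by_branch Named numeric vector mapping branch (child node
#'   label) to an omega override.
#' @return Object of class `codon_model`.
#' @export
codon_model <- function(code, kappa = 1, omega = 1, pi = NULL, gc = 0.5,
                        omega_by_branch = NULL) {
  stopifnot(is_genetic_code(code), kappa > 0, omega >= 0)
  if (is.null(pi)) {
    stopifnot(gc > 0, gc < 1)
    f <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    pi <- vapply(code$sense, function(cod) {
      prod(f[strsplit(cod, "")[[1]]])
    }, numeric(1))
    pi <- pi / sum(pi)
  } else {
    if (!is.null(names(pi))) pi <- pi[code$sense]
    if (length(pi) != length(code$sense)) {
      stop("pi must have one frequency per sense codon")
    }
    if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1 (within 1e-9)")
    pi <- stats::setNames(as.numeric(pi), code$sense)
  }
  structure(list(code = code, kappa = kappa, omega = omega, pi = pi,
                 omega_by_branch = omega_by_branch),
            class = "codon_model")
}

#' Build the scaled GY94 rate matrix
#'
#' Off-diagonal rate from codon i to j is nonzero only for
#' single-nucleotide differences: `q_ij = pi_j * kappa^[transition] *
#' omega^[nonsynonymous]`. The diagonal makes rows sum to zero and the
#' matrix is rescaled so the expected number of substitutions per codon per
#' unit branch length is 1 at stationarity. The parameterization is
#' time-reversible (`pi_i q_ij = pi_j q_ji`).
#'
#' @param model A [codon_model()].
#' @param omega Omega to use (defaults to the model's).
#' @return Rate matrix over the sense codons, with attribute `"pi"`.
#' @export
build_rate_matrix <- function(model, omega = model$omega) {
  code <- model$code
  sense <- code$sense
  ns <- length(sense)
  chars <- do.call(rbind, strsplit(sense, ""))
  q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  purine <- c("A", "G")
  for (i in seq_len(ns)) {
    diffs <- chars != matrix(chars[i, ], ns, 3, byrow = TRUE)
    nd <- rowSums(diffs)
    js <- which(nd == 1)
    for (j in js) {
      p <- which(diffs[j, ])
      from <- chars[i, p]; to <- chars[j, p]
      ts <- (from %in% purine) == (to %in% purine)
      syn <- code$codon_to_aa[sense[i]] == code$codon_to_aa[sense[j]]
      q[i, j] <- model$pi[j] *
        (if (ts) model$kappa else 1) * (if (syn) 1 else omega)
    }
  }
  diag(q) <- -rowSums(q)
  mu <- -sum(model$pi * diag(q))
  if (mu > 0) q <- q / mu
  attr(q, "pi") <- model$pi
  q
}

# transition probability matrix exp(t*Q) via eigendecomposition of the
# reversibility-symmetrized matrix; exact at this state-space size, no
# step-size tuning
transition_probabilities <- function(q, t) {
  pi <- attr(q, "pi")
  d <- sqrt(pi)
  s <- outer(d, 1 / d) * q        # symmetric for reversible q
  s <- (s + t(s)) / 2             # clean numerical asymmetry
  eig <- eigen(s, symmetric = TRUE)
  p <- outer(1 / d, d) *
    (eig$vectors %*% (exp(t * eig$values) * t(eig$vectors)))
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Simulate a codon alignment along a tree
#'
#' Draws the root sequence iid from the model's stationary frequencies and
#' evolves it along each branch with the matrix exponential of
#' (branch length x rate matrix), using that branch's omega override when
#' one is given (keyed by child node label). Output is gap-free; internal
#' node sequences are returned as well so that reconstruction oracles can
#' be tested against the simulation truth.
#'
#' @param tree A `phylo` object with branch lengths in expected
#'   substitutions per codon.
#' @param model A [codon_model()].
#' @param n_codons Number of codon sites.
#' @param seed Optional integer seed; fixes every random draw.
#' @return List with `codons` (character matrix over all nodes, rownames =
#'   tip then node labels), `tips` (named character vector of nucleotide
#'   strings), `tree` (with generated node labels), `model`.
#' @export
simulate_alignment <- function(tree, model, n_codons, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "codon_model"),
            n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- suppressWarnings(label_phylo(tree))
  sense <- model$code$sense
  ns <- length(sense)
  labels <- node_labels(tree)
  n_all <- length(labels)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- matrix(NA_integer_, n_all, n_codons)
  seqs[root, ] <- sample.int(ns, n_codons, replace = TRUE, prob = model$pi)
  pre <- ape::reorder.phylo(tree, "cladewise")
  p_cache <- list()
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; child <- pre$edge[e, 2]
    w <- model$omega
    ob <- model$omega_by_branch
    if (!is.null(ob) && labels[child] %in% names(ob)) {
      w <- ob[[labels[child]]]
    }
    t <- pre$edge.length[e]
    key <- sprintf("%.12g|%.12g", w, t)
    if (is.null(p_cache[[key]])) {
      p_cache[[key]] <- transition_probabilities(
        build_rate_matrix(model, omega = w), t)
    }
    p <- p_cache[[key]]
    parent_states <- seqs[par, ]
    child_states <- integer(n_codons)
    for (s in unique(parent_states)) {
      idx <- which(parent_states == s)
      child_states[idx] <- sample.int(ns, length(idx), replace = TRUE,
                                      prob = p[s, ])
    }
    seqs[child, ] <- child_states
  }
  codons <- matrix(sense[seqs], n_all, n_codons, dimnames = list(labels, NULL))
  tips <- apply(codons[seq_len(n_tip), , drop = FALSE], 1, paste,
                collapse = "")
  list(codons = codons, tips = tips, tree = tree, model = model)
}

#' Sample an iid codon-biased genome
#'
#' Generates genes emulating a genome under mutation pressure alone: per
#' codon an amino acid is drawn uniformly over the code's synonymous
#' families, then a codon within the family is chosen with third-position
#' nucleotide probabilities tilted toward a GC3 target (G and C share
#' `gc3_target`, A and T share `1 - gc3_target`, renormalized over the
#' family's available third positions). With `gc3_target = 0.25` this is
#' the AT-rich *Tetrahymena*-like background; a shifted target (e.g. 0.8)
#' yields the "alien" positive control for the HGT screen.
#'
#' @param n_genes Number of genes.
#' @param codons_per_gene Codons per gene.
#' @param gc3_target Target third-position GC fraction, in (0, 1).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param code A [genetic_code()] object (default: ciliate nuclear,
#'   table 6).
#' @param prefix Gene id prefix.
#' @return List of `coding_sequence` objects.
#' @export
sample_biased_genome <- function(n_genes, codons_per_gene, gc3_target,
                                 seed = NULL, code = genetic_code(6),
                                 prefix = "gene") {
  stopifnot(gc3_target > 0, gc3_target < 1, n_genes >= 1,
            codons_per_gene >= 1)
  if (!is.null(seed)) set.seed(seed)
  w3 <- c(A = (1 - gc3_target) / 2, C = gc3_target / 2,
          G = gc3_target / 2, T = (1 - gc3_target) / 2)
  fams <- code$families
  fam_codons <- unname(fams)
  fam_probs <- lapply(fams, function(cods) {
    w <- w3[substr(cods, 3, 3)]
    w / sum(w)
  })
  lapply(seq_len(n_genes), function(g) {
    fam_idx <- sample.int(length(fams), codons_per_gene, replace = TRUE)
    codons <- vapply(fam_idx, function(fi) {
      sample(fam_codons[[fi]], 1L, prob = fam_probs[[fi]])
    }, character(1))
    new_coding_sequence(sprintf("%s_%03d", prefix, g), codons, code)
  })
}

#' Gene-duplication scenario with a relaxed post-duplication stem
#'
#' Builds the synthetic analogue of a duplication-then-purifying-selection
#' history: a rooted tree with two clades, the stem branch of one clade
#' (the branch immediately following the duplication) evolving under
#' relaxed constraint (`omega_stem = 0.48` by default) while every other
#' branch evolves under strong purifying selection
#' (`omega_background = 0.06`). Defaults mirror the *Tetrahymena* FAD
#' study scale: 300 codons, 20 tips, `kappa = 2`, AT-rich frequencies
#' (F1x4 from GC 0.25) under the ciliate nuclear code. The bundle contains
#' everything [branch_omega()] needs plus the ground truth.
#'
#' @param seed Integer seed; the bundle is reproducible bit for bit.
#' @param n_codons Codon sites (default 300).
#' @param tips_per_clade Tips per clade (default 10, i.e. 20 tips total).
#' @param omega_background,omega_stem Background and stem dN/dS.
#' @param kappa Transition/transversion ratio (default 2).
#' @param gc GC content for F1x4 frequencies (default 0.25, AT-rich).
#' @param code Genetic code (default table 6).
#' @param stem_length,clade_depth,other_stem_length Branch-length knobs in
#'   expected substitutions per codon.
#' @return Object of class `duplication_scenario`: list with `tree`,
#'   `codons` (tip codon matrix), `tips`, `omega_true` (named per-branch
#'   omega, by child label), `stem_branch` (child label of the elevated
#'   branch), `clades` (named list of the two clades' tip labels),
#'   `model`.
#' @export
duplication_scenario <- function(seed = 1, n_codons = 300,
                                 tips_per_clade = 10,
                                 omega_background = 0.06, omega_stem = 0.48,
                                 kappa = 2, gc = 0.25,
                                 code = genetic_code(6),
                                 stem_length = 0.3, clade_depth = 0.15,
                                 other_stem_length = 0.1) {
  set.seed(seed)
  clade_newick <- function(n, prefix, depth) {
    phy <- ape::rcoal(n, tip.label = sprintf("%s%02d", prefix, seq_len(n)))
    phy$edge.length <- phy$edge.length * depth /
      max(ape::node.depth.edgelength(phy))
    sub(";$", "", ape::write.tree(phy, digits = 10))
  }
  txt <- sprintf("(%s:%.10f,%s:%.10f);",
                 clade_newick(tips_per_clade, "dup", clade_depth),
                 stem_length,
                 clade_newick(tips_per_clade, "out", clade_depth),
                 other_stem_length)
  tree <- label_phylo(ape::read.tree(text = txt))
  labels <- node_labels(tree)
  dup_tips <- grep("^dup", tree$tip.label, value = TRUE)
  out_tips <- grep("^out", tree$tip.label, value = TRUE)
  stem_node <- ape::getMRCA(tree, match(dup_tips, tree$tip.label))
  stem_label <- labels[stem_node]
  omega_true <- stats::setNames(
    rep(omega_background, nrow(tree$edge)), labels[tree$edge[, 2]])
  omega_true[stem_label] <- omega_stem
  model <- codon_model(code, kappa = kappa, omega = omega_background,
                       gc = gc,
                       omega_by_branch = omega_true[stem_label])
  sim <- simulate_alignment(tree, model, n_codons)
  n_tip <- length(tree$tip.label)
  structure(list(tree = tree,
                 codons = sim$codons[seq_len(n_tip), , drop = FALSE],
                 tips = sim$tips,
                 omega_true = omega_true, stem_branch = stem_label,
                 clades = list(duplicated = dup_tips, outgroup = out_tips),
                 model = model, seed = seed),
            class = "duplication_scenario")
}

#' @export
print.duplication_scenario <- function(x, ...) {
  cat(sprintf(
    "<duplication_scenario> seed %d: %d tips, %d codons, stem branch '%s' (omega %.2f) over background omega %.2f\n",
    x$seed, length(x$tips), ncol(x$codons), x$stem_branch,
    x$omega_true[[x$stem_branch]],
    min(x$omega_true)))
  invisible(x)
}
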