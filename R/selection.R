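# Nei-Gojobori (1986) counting machinery. Site fractions per codon and
# pathway-averaged difference counts per codon pair are precomputed once
# per genetic code and cached, making pairwise and branch-wise estimation
# a table lookup.

.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function(code) {
  key <- code$table_id
  if (!is.null(.ng86_env[[key]])) return(.ng86_env[[key]])
  sense <- code$sense
  aa <- code$codon_to_aa
  nt <- c("A", "C", "G", "T")
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  # single-nucleotide neighbours of each codon
  neighbours <- function(cod) {
    out <- character(0)
    for (p in 1:3) {
      for (b in setdiff(nt, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        out <- c(out, alt)
      }
    }
    out
  }
  # per-codon site fractions with stop-path renormalization: at each
  # position the unit site mass is spread over the non-stop changes; if all
  # three changes create stops the position contributes nothing.
  s_sites <- n_sites <- stats::setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    s <- 0; n <- 0
    for (p in 1:3) {
      alts <- vapply(setdiff(nt, substr(cod, p, p)), function(b) {
        alt <- cod; substr(alt, p, p) <- b; alt
      }, character(1))
      ok <- alts[aa[alts] != "*"]
      if (length(ok) == 0) next
      syn <- sum(aa[ok] == aa[cod]) / length(ok)
      s <- s + syn
      n <- n + 1 - syn
    }
    s_sites[cod] <- s
    n_sites[cod] <- n
  }
  # pathway-averaged differences for every sense-codon pair
  ns <- length(sense)
  sd_mat <- matrix(0, ns, ns, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  ok_mat <- matrix(TRUE, ns, ns, dimnames = list(sense, sense))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j <= i) next
      a <- sense[i]; b <- sense[j]
      pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (length(pos) == 0) next
      paths <- path_counts(a, b, pos, aa)
      if (paths$n == 0) {
        ok_mat[i, j] <- ok_mat[j, i] <- FALSE
      } else {
        sd_mat[i, j] <- sd_mat[j, i] <- paths$syn / paths$n
        nd_mat[i, j] <- nd_mat[j, i] <- paths$nonsyn / paths$n
      }
    }
  }
  tab <- list(sense = sense, s_sites = s_sites, n_sites = n_sites,
              sd = sd_mat, nd = nd_mat, ok = ok_mat)
  .ng86_env[[key]] <- tab
  tab
}

# enumerate orderings of the differing positions; paths through stop
# codons are excluded; returns summed syn/nonsyn step counts over
# surviving paths and their number
path_counts <- function(a, b, pos, aa) {
  perms <- permutations(pos)
  syn <- 0; nonsyn <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- a
    steps_syn <- 0; steps_non <- 0
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (aa[nxt] == "*") { valid <- FALSE; break }
      if (aa[nxt] == aa[cur]) steps_syn <- steps_syn + 1
      else steps_non <- steps_non + 1
      cur <- nxt
    }
    if (valid) {
      syn <- syn + steps_syn
      nonsyn <- nonsyn + steps_non
      n_ok <- n_ok + 1L
    }
  }
  list(syn = syn, nonsyn = nonsyn, n = n_ok)
}

permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Nei-Gojobori (1986) site counting with stop exclusion: at each of the
#' three positions the three single-nucleotide changes are considered,
#' changes to stop codons are excluded and the position's unit site mass is
#' renormalized over the remaining changes (a position whose three changes
#' all create stops contributes nothing).
#'
#' @param codon A sense codon.
#' @param code A [genetic_code()] object.
#' @return Named numeric `c(s = , n = )` with `s + n <= 3`.
#' @examples
#' ng86_sites("TTT", genetic_code(1))  # s = 1/3, n = 8/3
#' @export
ng86_sites <- function(codon, code) {
  stopifnot(is_genetic_code(code))
  codon <- toupper(codon)
  if (!codon %in% code$sense) {
    stop("not a sense codon under table ", code$table_id, ": ", codon)
  }
  tab <- ng86_tables(code)
  c(s = unname(tab$s_sites[codon]), n = unname(tab$n_sites[codon]))
}

#' Pairwise dN/dS by the Nei-Gojobori counting method
#'
#' Site counts are averaged over the two sequences; per differing codon
#' pair, synonymous and nonsynonymous differences are averaged over all
#' minimal mutational pathways that do not pass through a stop codon
#' (codon pairs with no surviving pathway are skipped and tallied).
#' Proportions are Jukes-Cantor corrected:
#' `d = -3/4 * log(1 - 4p/3)`. Codon columns where either sequence has a
#' gap or ambiguity are dropped pairwise.
#'
#' @param a,b `coding_sequence` objects of equal codon length bound to the
#'   same genetic code, or plain codon character vectors (then `code` is
#'   required).
#' @param code Genetic code, only needed for plain codon vectors.
#' @return Object of class `ng86`: list with `S`, `N` (site counts), `Sd`,
#'   `Nd` (differences), `pS`, `pN`, `dS`, `dN`, `omega` (`NA` when
#'   `dS == 0`), `codons_used`, `codons_skipped`.
#' @export
ng86_pair <- function(a, b, code = NULL) {
  if (inherits(a, "coding_sequence")) {
    if (is.null(code)) code <- a$code
    a <- a$codons
  }
  if (inherits(b, "coding_sequence")) {
    if (is.null(code)) code <- b$code
    b <- b$codons
  }
  stopifnot(is_genetic_code(code))
  if (length(a) != length(b)) {
    stop("sequences differ in codon length: ", length(a), " vs ", length(b))
  }
  tab <- ng86_tables(code)
  usable <- a %in% tab$sense & b %in% tab$sense
  a <- a[usable]; b <- b[usable]
  if (length(a) == 0) stop("no usable codon columns")
  blocked <- !tab$ok[cbind(a, b)]
  skipped <- sum(blocked) + sum(!usable)
  au <- a[!blocked]; bu <- b[!blocked]
  S <- (sum(tab$s_sites[au]) + sum(tab$s_sites[bu])) / 2
  N <- (sum(tab$n_sites[au]) + sum(tab$n_sites[bu])) / 2
  Sd <- sum(tab$sd[cbind(au, bu)])
  Nd <- sum(tab$nd[cbind(au, bu)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p, which) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) {
      stop("Jukes-Cantor correction undefined for ", which,
           " (proportion ", signif(p, 4), " >= 0.75)")
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS, "dS")
  dN <- jc(pN, "dN")
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 codons_used = length(au), codons_skipped = skipped),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf(
    "<ng86> S=%.2f N=%.2f Sd=%.2f Nd=%.2f dS=%.4f dN=%.4f omega=%s (%d codons, %d skipped)\n",
    x$S, x$N, x$Sd, x$Nd, x$dS, x$dN,
    if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega),
    x$codons_used, x$codons_skipped))
  invisible(x)
}

#' Fitch parsimony reconstruction of ancestral codon sequences
#'
#' Per codon column, Fitch parsimony over the sense-codon state set:
#' bottom-up intersection/union, then top-down assignment in which the root
#' takes the lexicographically smallest state of its set and each child
#' takes its parent's state when that state is in its own set, otherwise
#' its set's lexicographically smallest member. Ties are therefore broken
#' deterministically. Columns containing a gap or non-sense codon in any
#' tip are dropped (complete deletion) with a message. The reconstruction
#' attains the Fitch parsimony length on binary trees; on multifurcations
#' the same reduce-based rule is applied as an approximation.
#'
#' @param tree A `phylo` object with unique, non-empty node labels (see
#'   [read_newick()]).
#' @param tip_codons Character matrix of codons, rows named by tip label.
#' @param code A [genetic_code()] object.
#' @return List with `codons` (matrix over all nodes, rownames = tip then
#'   node labels), `changes` (total parsimony length over kept columns),
#'   `kept_columns` (indices into the input columns).
#' @export
fitch_ancestral <- function(tree, tip_codons, code) {
  stopifnot(inherits(tree, "phylo"), is_genetic_code(code))
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    tree <- label_phylo(tree)
  }
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(tip_codons))
  if (length(missing) > 0) {
    stop("tip label(s) absent from alignment: ",
         paste(missing, collapse = ", "))
  }
  m <- tip_codons[tips, , drop = FALSE]
  keep <- apply(m, 2, function(col) all(col %in% code$sense))
  if (!all(keep)) {
    message("fitch_ancestral: dropped ", sum(!keep),
            " column(s) with gaps or non-sense codons (complete deletion)")
  }
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) stop("no usable codon columns after complete deletion")
  n_tip <- length(tips)
  n_node <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")$edge
  root <- post[nrow(post), 1]
  labels <- node_labels(tree)
  anc <- matrix(NA_character_, n_tip + n_node, ncol(m),
                dimnames = list(labels, NULL))
  anc[seq_len(n_tip), ] <- m
  changes <- 0L
  for (col in seq_len(ncol(m))) {
    sets <- vector("list", n_tip + n_node)
    for (i in seq_len(n_tip)) sets[[i]] <- m[i, col]
    # bottom-up: postorder guarantees a child's set is complete before any
    # edge above it is visited; reduce each parent's children pairwise
    for (e in seq_len(nrow(post))) {
      par <- post[e, 1]; child <- post[e, 2]
      if (is.null(sets[[par]])) {
        sets[[par]] <- sets[[child]]
      } else {
        inter <- intersect(sets[[par]], sets[[child]])
        if (length(inter) > 0) {
          sets[[par]] <- inter
        } else {
          sets[[par]] <- sort(union(sets[[par]], sets[[child]]))
          changes <- changes + 1L
        }
      }
    }
    # top-down assignment
    state <- character(n_tip + n_node)
    state[root] <- sort(sets[[root]])[1]
    pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
    for (e in seq_len(nrow(pre))) {
      par <- pre[e, 1]; child <- pre[e, 2]
      if (state[par] %in% sets[[child]]) {
        state[child] <- state[par]
      } else {
        state[child] <- sort(sets[[child]])[1]
      }
    }
    anc[(n_tip + 1):(n_tip + n_node), col] <-
      state[(n_tip + 1):(n_tip + n_node)]
  }
  list(codons = anc, changes = changes, kept_columns = which(keep))
}

#' Branch-wise dN/dS over a tree (free-ratio approximation)
#'
#' Approximates a free-ratio branch model by counting: ancestral codon
#' sequences are reconstructed by Fitch parsimony and the Nei-Gojobori
#' estimator is applied to each (parent, child) branch. Named clades are
#' aggregated by pooling S, N, Sd and Nd over the branches of the induced
#' subtree (the paths from the members' most recent common ancestor down to
#' the members) before distance correction -- never by averaging per-branch
#' omegas. Branches with `dS = 0` report `omega = NA`.
#'
#' @param tree A `phylo` object.
#' @param tip_codons Character matrix of codons, rows named by tip label.
#' @param code A [genetic_code()] object.
#' @param clades Optional named list mapping clade name to a character
#'   vector of leaf labels.
#' @return Object of class `branch_omega`: list with `branches` (one row
#'   per tree branch: `parent`, `child`, `length`, `S`, `N`, `Sd`, `Nd`,
#'   `dS`, `dN`, `omega`) and `clades` (pooled rows, or NULL).
#' @export
branch_omega <- function(tree, tip_codons, code, clades = NULL) {
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    tree <- label_phylo(tree)
  }
  rec <- fitch_ancestral(tree, tip_codons, code)
  labels <- node_labels(tree)
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    r <- ng86_pair(rec$codons[labels[par], ], rec$codons[labels[child], ],
                   code = code)
    data.frame(parent = labels[par], child = labels[child],
               length = if (is.null(tree$edge.length)) NA_real_
                        else tree$edge.length[e],
               S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               dS = r$dS, dN = r$dN, omega = r$omega,
               stringsAsFactors = FALSE)
  })
  branches <- do.call(rbind, rows)
  clade_df <- NULL
  if (!is.null(clades)) {
    clade_df <- do.call(rbind, lapply(names(clades), function(nm) {
      edges <- induced_edges(tree, clades[[nm]])
      sel <- branches$child %in% labels[edges]
      pool_ng86(branches[sel, ], nm)
    }))
  }
  structure(list(branches = branches, clades = clade_df),
            class = "branch_omega")
}

# child node numbers of the edges in the subtree induced by `leaves`
# (paths from their MRCA down to each leaf)
induced_edges <- function(tree, leaves) {
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx)) {
    stop("leaf label(s) not in tree: ",
         paste(leaves[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 1) return(idx)
  mrca <- ape::getMRCA(tree, idx)
  parent_of <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
  nodes <- integer(0)
  for (tip in idx) {
    cur <- tip
    while (cur != mrca) {
      nodes <- c(nodes, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  unique(nodes)
}

# pool NG86 counts over branch rows, then correct distances
pool_ng86 <- function(rows, name) {
  S <- sum(rows$S); N <- sum(rows$N)
  Sd <- sum(rows$Sd); Nd <- sum(rows$Nd)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  data.frame(clade = name, n_branches = nrow(rows), S = S, N = N,
             Sd = Sd, Nd = Nd, dS = dS, dN = dN, omega = omega,
             stringsAsFactors = FALSE)
}

#' @export
print.branch_omega <- function(x, ...) {
  cat(sprintf("<branch_omega> %d branches\n", nrow(x$branches)))
  print(utils::head(x$branches, 10), row.names = FALSE)
  if (nrow(x$branches) > 10) cat("...\n")
  if (!is.null(x$clades)) {
    cat("clade aggregates:\n")
    print(x$clades, row.names = FALSE)
  }
  invisible(x)
}
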