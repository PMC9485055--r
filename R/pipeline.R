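#' Run the parametric HGT screen end to end
#'
#' Reads a candidate gene family and a host-genome background (CDS FASTA),
#' validates every record (malformed records are reported and dropped; the
#' run continues while at least `min_family` family and `min_background`
#' background genes survive), optionally filters the family by the
#' tripartite histidine motif on the translated sequences, runs
#' [hgt_screen()], and writes all artifacts to `out_dir`: the per-gene
#' codon-usage table (`cub.tsv`), PR2 points (`pr2.tsv`), PCA scores
#' (`pca.tsv`), the neutrality fit (`neutrality.json`), the machine-readable
#' report (`report.json`), a human-readable `summary.txt`, and the resolved
#' configuration (`config.json`). Every number in the text summary exists
#' in the JSON report.
#'
#' @param family Path to the family CDS FASTA, or a named character vector
#'   of nucleotide sequences.
#' @param background Same, for the background gene set.
#' @param code Genetic code table id (default 6, ciliate nuclear) or a
#'   [genetic_code()] object.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param motif Optional PROSITE-style pattern applied to translated family
#'   sequences before the screen (e.g. [fad_tripartite_motif()]).
#' @param min_family,min_background Minimum surviving gene counts.
#' @return The [hgt_screen()] report, with a `dropped` attribute listing
#'   per-record validation failures, invisibly.
#' @export
run_hgt_screen <- function(family, background, code = 6, out_dir = NULL,
                           motif = NULL, min_family = 1,
                           min_background = 10) {
  if (!is_genetic_code(code)) code <- genetic_code(code)
  read_set <- function(x) {
    if (length(x) == 1 && is.null(names(x))) {
      read_fasta(x, alphabet = "nucleotide")
    } else x
  }
  fam_seqs <- read_set(family)
  bg_seqs <- read_set(background)
  validate_set <- function(seqs) {
    dropped <- character(0)
    kept <- list()
    for (id in names(seqs)) {
      cds <- tryCatch(validate_cds(seqs[[id]], code, id = id),
                      error = function(e) conditionMessage(e))
      if (is.character(cds)) dropped <- c(dropped, cds)
      else kept[[id]] <- cds
    }
    list(kept = kept, dropped = dropped)
  }
  fam_v <- validate_set(fam_seqs)
  bg_v <- validate_set(bg_seqs)
  dropped <- c(fam_v$dropped, bg_v$dropped)
  for (msg in dropped) message("dropped record: ", msg)
  fam_cds <- fam_v$kept
  if (!is.null(motif)) {
    prot <- vapply(fam_cds, translate_cds, character(1))
    keep <- names(filter_by_motif(prot, motif)$kept)
    fam_cds <- fam_cds[keep]
  }
  if (length(fam_cds) < min_family) {
    stop("fewer than ", min_family, " family genes survive validation")
  }
  if (length(bg_v$kept) < min_background) {
    stop("fewer than ", min_background, " background genes survive validation")
  }
  report <- hgt_screen(fam_cds, bg_v$kept)
  attr(report, "dropped") <- dropped
  if (!is.null(out_dir)) {
    write_hgt_artifacts(report, out_dir,
                        config = list(screen = "hgt",
                                      code_table = code$table_id,
                                      motif = motif,
                                      n_family = length(fam_cds),
                                      n_background = length(bg_v$kept)))
  }
  invisible(report)
}

write_hgt_artifacts <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) {
    utils::write.table(d, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$stats[, c("id", "set", "n_codons", "gc3s", "gc12", "gc3",
                       "enc", "enc_expected")], "cub.tsv")
  tsv(report$stats[, c("id", "set", "pr2_at", "pr2_gc")], "pr2.tsv")
  sc <- data.frame(id = rownames(report$pca$scores),
                   set = report$stats$set,
                   report$pca$scores[, seq_len(min(4, ncol(report$pca$scores))),
                                     drop = FALSE])
  tsv(sc, "pca.tsv")
  if (!is.null(report$neutrality)) {
    jsonlite::write_json(unclass(report$neutrality),
                         file.path(out_dir, "neutrality.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  json_report <- list(
    tests = report$tests,
    p_value = report$p_value,
    verdict = report$verdict,
    neutrality = if (is.null(report$neutrality)) NULL
                 else unclass(report$neutrality),
    pca_variance_fraction = report$pca$variance_fraction[1:2],
    n_family = sum(report$stats$set == "family"),
    n_background = sum(report$stats$set == "background"))
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  summary_lines <- c(
    sprintf("Parametric HGT screen: %d family vs %d background genes",
            json_report$n_family, json_report$n_background),
    sprintf("rank-sum ENc: p = %s (BH-adjusted %s)",
            format(report$tests$p_raw[1]), format(report$tests$p_adj[1])),
    sprintf("rank-sum GC3s: p = %s (BH-adjusted %s)",
            format(report$tests$p_raw[2]), format(report$tests$p_adj[2])),
    sprintf("headline adjusted p = %s", format(report$p_value)),
    sprintf("verdict: family is %s", report$verdict))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Run the duplication (branch selective-pressure) screen end to end
#'
#' Reads an aligned CDS FASTA and a Newick tree, reconstructs ancestral
#' codon sequences by Fitch parsimony, estimates per-branch dN/dS with the
#' Nei-Gojobori counting method ([branch_omega()]; a counting
#' approximation to a CODEML free-ratio branch model, and labeled as such
#' in the report), pools named clades, and writes `branches.tsv`,
#' `clades.tsv`, `report.json`, `summary.txt` and `config.json` to
#' `out_dir`.
#'
#' @param alignment Path to an aligned CDS FASTA (gapped allowed; gapped
#'   codon columns are dropped), or a codon character matrix with tip
#'   rownames.
#' @param tree Path to a Newick file, or a `phylo` object.
#' @param clades Named list mapping clade name to leaf labels, or a path
#'   to a JSON file with that mapping.
#' @param code Genetic code table id or [genetic_code()] object.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return The [branch_omega()] table, invisibly.
#' @export
run_duplication_screen <- function(alignment, tree, clades = NULL,
                                   code = 6, out_dir = NULL) {
  if (!is_genetic_code(code)) code <- genetic_code(code)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(alignment) && !is.matrix(alignment)) {
    seqs <- read_fasta(alignment, alphabet = "nucleotide")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop("alignment sequences differ in length")
    }
    if (lens[1] %% 3 != 0) stop("alignment length not divisible by 3")
    tip_codons <- do.call(rbind, lapply(seqs, split_codons))
  } else {
    tip_codons <- alignment
  }
  extra_tree <- setdiff(tree$tip.label, rownames(tip_codons))
  extra_aln <- setdiff(rownames(tip_codons), tree$tip.label)
  if (length(extra_tree) > 0 || length(extra_aln) > 0) {
    stop("tree/alignment label mismatch; in tree only: [",
         paste(extra_tree, collapse = ", "), "]; in alignment only: [",
         paste(extra_aln, collapse = ", "), "]")
  }
  if (is.character(clades)) {
    clades <- jsonlite::read_json(clades, simplifyVector = TRUE)
  }
  res <- branch_omega(tree, tip_codons, code, clades = clades)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res$branches, file.path(out_dir, "branches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$clades)) {
      utils::write.table(res$clades, file.path(out_dir, "clades.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    json_report <- list(
      method = paste("NG86 counting on Fitch-parsimony ancestors;",
                     "an approximation to a free-ratio (per-branch omega)",
                     "codon model, not a maximum-likelihood fit"),
      branches = res$branches,
      clades = res$clades)
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(list(screen = "duplication",
                              code_table = code$table_id,
                              clades = clades),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    lines <- c(sprintf("Branch selective-pressure screen: %d branches",
                       nrow(res$branches)))
    if (!is.null(res$clades)) {
      lines <- c(lines, sprintf(
        "clade '%s': pooled omega = %s", res$clades$clade,
        format(res$clades$omega)))
    }
    writeLines(lines, file.path(out_dir, "summary.txt"))
  }
  invisible(res)
}
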