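#' Genetic code tables with synonymous-family structure
#'
#' Builds a genetic code object from an NCBI translation table and derives
#' the synonymous-family structure that every downstream codon-usage and
#' dN/dS statistic is parameterized by. Table 1 is the standard code
#' (61 sense codons); table 6 is the ciliate nuclear code used by
#' *Tetrahymena*, in which TAA and TAG encode glutamine and only TGA is a
#' stop (63 sense codons).
#'
#' @param table NCBI translation table identifier; `1` (standard) or `6`
#'   (ciliate nuclear). Character or numeric.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character over all 64 codons, `"*"`
#'   for stops), `sense` (sense codons), `stops`, `families` (list mapping
#'   amino acid to its synonymous codons), `degeneracy` (named integer per
#'   sense codon), and `fourfold_boxes` (complete synonymous quartets:
#'   codon boxes whose four third-position variants all encode the same
#'   amino acid; used by parity-rule-2 statistics).
#' @examples
#' gc1 <- genetic_code(1)
#' table(lengths(gc1$families))  # 2 one-fold ... 3 six-fold families
#' gc6 <- genetic_code(6)
#' gc6$codon_to_aa[["TAA"]]      # "Q" under the ciliate nuclear code
#' @export
genetic_code <- function(table = 1) {
  table_id <- as.character(table)
  if (!table_id %in% c("1", "6")) {
    stop("unsupported genetic code table: ", table_id,
         " (supported: 1 standard, 6 ciliate nuclear)")
  }
  map <- Biostrings::getGeneticCode(table_id)
  # reorder to lexicographic codon order for stable downstream indexing
  cods <- all_codons()
  codon_to_aa <- stats::setNames(unname(map[cods]), cods)
  sense <- cods[codon_to_aa != "*"]
  stops <- cods[codon_to_aa == "*"]
  families <- split(sense, codon_to_aa[sense])
  degeneracy <- stats::setNames(
    lengths(families)[codon_to_aa[sense]], sense)
  # complete quartets: first-two-nucleotide boxes fully synonymous
  boxes <- split(cods, substr(cods, 1, 2))
  fourfold <- boxes[vapply(boxes, function(b) {
    aas <- codon_to_aa[b]
    all(aas != "*") && length(unique(aas)) == 1L
  }, logical(1))]
  structure(
    list(table_id = table_id, codon_to_aa = codon_to_aa, sense = sense,
         stops = stops, families = families,
         degeneracy = degeneracy, fourfold_boxes = fourfold),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code table %s: %d sense codons, %d stops (%s)\n",
              x$table_id, length(x$sense), length(x$stops),
              paste(x$stops, collapse = ", ")))
  deg <- table(lengths(x$families))
  cat("Synonymous families by degeneracy:",
      paste(sprintf("%s-fold: %d", names(deg), deg), collapse = ", "), "\n")
  invisible(x)
}

# All 64 codons in lexicographic (A < C < G < T) order.
all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(n3 = nt, n2 = nt, n1 = nt, stringsAsFactors = FALSE)
  sort(paste0(g$n1, g$n2, g$n3))
}

# Split a nucleotide string into its codon vector (length must be
# divisible by 3; unchecked here, callers validate).
split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

is_genetic_code <- function(x) inherits(x, "genetic_code")
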