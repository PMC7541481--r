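CLADES <- c("XLR", "NaR", "XeR", "CyHR", "CyR")
HABITATS <- c("Marine", "Freshwater", "Saline", "NA")
SUBCLADES <- c(LETTERS[1:7], "NA")

#' Validate a genome-record table
#'
#' A genome record carries the genome id, its phylogenomic subclade (A-G or
#' NA), habitat (marine / freshwater / saline / NA), a retinal-biosynthesis
#' (diox1) presence flag, and the clade labels of its rhodopsin genes.
#'
#' @param records data.frame with columns `genome_id`, `subclade`, `habitat`,
#'   `diox1_present`, and `genes` (list column of clade-label character
#'   vectors; empty vector = no rhodopsin genes).
#' @return The validated records, invisibly.
#' @export
validate_genome_records <- function(records) {
  need <- c("genome_id", "subclade", "habitat", "diox1_present", "genes")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad <- which(!records$subclade %in% SUBCLADES)
  if (length(bad)) stop("unknown subclade for genome ", records$genome_id[bad[1]])
  bad <- which(!tolower(records$habitat) %in% tolower(HABITATS))
  if (length(bad)) stop("unknown habitat for genome ", records$genome_id[bad[1]])
  for (i in seq_len(nrow(records))) {
    g <- records$genes[[i]]
    if (length(g) && !all(g %in% CLADES))
      stop("unknown rhodopsin clade label for genome ", records$genome_id[i])
  }
  invisible(records)
}

#' Tabulate the habitat-by-clade rhodopsin distribution
#'
#' Builds the survey summary table: one row per subclade plus a Total row.
#' Clade columns count rhodopsin genes; habitat columns count genomes that
#' possess at least one rhodopsin gene. "High salinity" habitats map to the
#' `Saline` column.
#'
#' @param records genome records as in [validate_genome_records()]; may be
#'   empty (all-zero table).
#' @return A data.frame of class `habitat_table` with columns `subclade`,
#'   `possessing_genomes`, `all_genomes`, one per clade, `gene_total`,
#'   `Marine`, `Freshwater`, `Saline`, `NA.` (habitat unknown).
#' @export
tabulate_habitat <- function(records) {
  if (nrow(records)) validate_genome_records(records)
  hab_norm <- HABITATS[match(tolower(records$habitat), tolower(HABITATS))]
  ngenes <- vapply(records$genes, length, integer(1))
  rows <- lapply(SUBCLADES, function(sc) {
    idx <- which(records$subclade == sc)
    poss <- idx[ngenes[idx] > 0L]
    genes <- unlist(records$genes[idx])
    cl <- vapply(CLADES, function(x) sum(genes == x), integer(1))
    hb <- vapply(HABITATS, function(h) sum(hab_norm[poss] == h), integer(1))
    data.frame(subclade = sc, possessing_genomes = length(poss),
               all_genomes = length(idx), as.list(cl), gene_total = sum(cl),
               setNames(as.list(hb), c("Marine", "Freshwater", "Saline", "NA.")),
               check.names = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  total <- tab[1, , drop = FALSE]
  total$subclade <- "Total"
  for (cn in setdiff(names(tab), "subclade")) total[[cn]] <- sum(tab[[cn]])
  out <- rbind(tab, total)
  rownames(out) <- NULL
  class(out) <- c("habitat_table", "data.frame")
  out
}

#' @export
print.habitat_table <- function(x, ...) {
  cat("Rhodopsin distribution and habitats\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Synthetic 154-genome survey fixture
#'
#' A deterministic, synthetic reconstruction of a published cyanobacterial
#' rhodopsin survey, matching its prose-stated marginal counts exactly:
#' 154 genomes, 42 of them possessing 56 rhodopsin genes in total
#' (XLR 3, NaR 1, XeR 15, CyHR 24, CyR 13); possessing genomes split
#' 2 marine / 29 freshwater / 9 saline / 2 habitat-unknown; 152 of 154
#' genomes carrying the retinal-biosynthesis gene diox1. The per-subclade
#' allocation is synthetic (only the marginals are anchored): subclades A,
#' C, F and G (56 genomes) carry no rhodopsins, and the possessing genomes
#' sit in B (11), D (19), E (10) and NA (2).
#'
#' @return A genome-records data.frame as accepted by [tabulate_habitat()].
#' @export
cyanobacteria_survey_fixture <- function() {
  genes <- c(rep("XLR", 3), rep("NaR", 1), rep("XeR", 15),
             rep("CyHR", 24), rep("CyR", 13))            # 56 genes
  # 42 possessing genomes: the first 14 get two genes, the rest one
  per_genome <- c(rep(2L, 14), rep(1L, 28))
  stopifnot(sum(per_genome) == length(genes))
  gene_lists <- split(genes, rep(seq_along(per_genome), per_genome))
  habitat <- c(rep("marine", 2), rep("freshwater", 29),
               rep("saline", 9), rep("NA", 2))
  subclade <- c(rep("B", 11), rep("D", 19), rep("E", 10), rep("NA", 2))
  poss <- data.frame(genome_id = sprintf("possessing_%02d", 1:42),
                     subclade = subclade, habitat = habitat,
                     diox1_present = TRUE)
  poss$genes <- unname(gene_lists)
  empty <- data.frame(
    genome_id = sprintf("nonpossessing_%03d", 1:112),
    subclade = c(rep("A", 13), rep("C", 36), rep("F", 4), rep("G", 3),
                 rep("B", 34), rep("D", 1), rep("E", 21)),
    habitat = c(rep("marine", 60), rep("freshwater", 40), rep("saline", 8),
                rep("NA", 4)),
    diox1_present = c(rep(FALSE, 2), rep(TRUE, 110)))
  empty$genes <- replicate(112, character(0), simplify = FALSE)
  rbind(poss, empty)
}
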