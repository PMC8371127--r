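# Study-design reference tables for the Holomycota analyses this
# package targets: the functional-category breakdown of the hyphal
# morphogenesis protein inventory and the composition of the taxon
# samplings. Shipped as plain constants so bookkeeping can be checked
# without any external download.

#' Functional categories of the hyphal morphogenesis inventory
#'
#' The 619-protein hyphal multicellularity inventory (362 gene
#' families) grouped into ten functional categories, with the number of
#' proteins per category.
#'
#' @return named integer vector: category -> number of proteins.
#' @export
hyphal_category_sizes <- function() {
  c("actin cytoskeleton" = 55L,
    "adhesion" = 30L,
    "polarity maintenance" = 107L,
    "cell wall biogenesis/remodelling" = 92L,
    "septation" = 56L,
    "signalling" = 82L,
    "transcriptional regulation" = 51L,
    "vesicle transport" = 103L,
    "microtubule-based transport" = 32L,
    "cell cycle regulation" = 11L)
}

#' Write a trait-to-category map with the hyphal category sizes
#'
#' Emits a two-column TSV (trait, category) whose categories have
#' exactly the sizes of [hyphal_category_sizes()]. Trait identifiers
#' are synthetic placeholders (`trait0001` ...): the real protein names
#' live in the study's supplementary material, but the bookkeeping
#' (sizes and total) only needs the counts.
#'
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_hyphal_category_map <- function(path) {
  sizes <- hyphal_category_sizes()
  df <- data.frame(
    trait = sprintf("trait%04d", seq_len(sum(sizes))),
    category = rep(names(sizes), sizes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Taxon-sampling composition of the expanded phylogenomic dataset
#'
#' Breakdown of the 74-species taxon sampling (the dataset that adds
#' the long-branching core Microsporidia and metchnikovellids):
#' Opisthokonta, Amoebozoa and Apusomonadida counts.
#'
#' @return data frame with columns `group` and `n_species`.
#' @export
taxon_sampling_composition <- function() {
  data.frame(group = c("Opisthokonta", "Amoebozoa", "Apusomonadida"),
             n_species = c(71L, 2L, 1L))
}
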