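#' Ring atom names used in the stacking analysis
#'
#' The nine heavy atoms of the tryptophan indole ring and the nine
#' adenine-ring atoms of the allosteric nucleoside ligand (as named in the
#' deposited ligand topology), the two rings whose stacking defines the
#' adenosine-sandwich interaction.
#'
#' @name ring_atom_sets
NULL

#' @rdname ring_atom_sets
#' @export
indole_ring_atoms <- c("CG", "CD1", "NE1", "CE2", "CZ2", "CH2", "CZ3",
                       "CE3", "CD2")

#' @rdname ring_atom_sets
#' @export
adenine_ring_atoms <- c("N3", "C4", "N1", "C3", "C5", "N4", "C6", "N5", "C2")

#' Shipped transmembrane-helix residue ranges
#'
#' Curated (approximate) helix ranges for the dopamine transporter and the
#' serotonin/fly-transporter comparators, in each structure's full-length
#' numbering. Helix boundaries are inputs to the helix-comparison analyses,
#' never inferred; replace this table with ranges derived from your own
#' model's annotation where precision matters.
#'
#' @return Data frame with columns \code{structure, helix, chain, start,
#'   end}.
#' @export
helix_ranges <- function() {
  utils::read.csv(system.file("extdata", "helix_ranges.csv",
                              package = "bindsight"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Cross-species residue correspondence for core helices
#'
#' Expands the shipped per-helix offset table into a residue-level mapping
#' usable by \code{\link{pair_calpha}} and \code{\link{compare_helix}}. The
#' table is curated from published anchor residues (approximate; replace
#' with an alignment-derived table for production comparisons).
#'
#' @param pair Mapping identifier, e.g. \code{"hdat_hsert"} or
#'   \code{"hdat_ddat"}.
#' @param helices Optional helix names to restrict to (e.g.
#'   \code{c("TM3","TM8")}).
#' @return Data frame with columns \code{ref_chain, ref_resseq,
#'   target_chain, target_resseq, helix}.
#' @export
residue_mapping <- function(pair, helices = NULL) {
  tab <- utils::read.csv(system.file("extdata", "residue_mapping.csv",
                                     package = "bindsight"),
                         comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[tab$pair == pair, , drop = FALSE]
  if (!nrow(tab)) stop("unknown mapping pair: ", pair)
  if (!is.null(helices)) tab <- tab[tab$helix %in% helices, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    n <- r$ref_end - r$ref_start
    data.frame(ref_chain = r$ref_chain,
               ref_resseq = r$ref_start:(r$ref_start + n),
               target_chain = r$target_chain,
               target_resseq = r$target_start:(r$target_start + n),
               helix = r$helix, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
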