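#' Constant sequences used across designs and order sheets
#'
#' Returns the constant nucleotide sequences shared by every design: the
#' SpCas9 sgRNA scaffold, the tevopreQ1 3' stabilisation motif appended to
#' every epegRNA, the constant landing tails flanking each oligo-pool entry,
#' the BsaI-appending amplification extension, the modelled Golden-Gate
#' acceptor junctions, the Illumina Nextera-style adaptor tails used for
#' amplicon-sequencing primers, and the plasmid-pool amplicon-sequencing
#' primer pair for the U6-tevopreQ1 epegRNA cassette.
#'
#' The scaffold and motif are shipped as configurable constants taken from
#' the prime-editing plasmid literature; both can be overridden via
#' [design_params()].
#'
#' @return named list of character constants.
#' @export
pe_constants <- function() {
  list(
    scaffold_seq = paste0(
      "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTG",
      "GCACCGAGTCGGTGC"
    ),
    motif_seq = "CGCGGTTCTATCTAGTTACGCGTTAAACCAACTAGAA",
    pool_tail_left  = "ATGTGGGCAAGCACTACTCG",
    pool_tail_right = "CTTAGCAGTGGCTGTACGGA",
    ## 5' extension placed on both pool-amplification primers; carries the
    ## BsaI recognition site plus one spacer base so digestion cuts flush
    ## with the landing tails
    bsai_primer_ext = "TAAGGTCTCA",
    bsai_sites = c("GGTCTC", "GAGACC"),
    ## modelled Golden-Gate acceptor: sequence 5' and 3' of the insert in
    ## the reconstructed cassette (overhangs are the first/last 4 nt of the
    ## pool tails)
    acceptor_left  = "TTGTGGAAAGGACGAAAC",
    acceptor_right = "TTTTTTTGGATCCGGTAC",
    illumina_tail_f = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
    illumina_tail_r = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
    ampseq_primer_f = paste0(
      "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
      "ATATATCTTGTGGAAAGGACGAAAC"
    ),
    ampseq_primer_r = paste0(
      "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
      "TACCTCGAGCGGCCCA"
    )
  )
}

#' Design parameters for epegRNA and nicking-gRNA construction
#'
#' Bundles the tunable geometry and library parameters used throughout the
#' design stage. Defaults follow common prime-editing practice: a 13-nt
#' primer-binding site, the SpCas9 nick between protospacer bases 17 and 18,
#' a reverse-transcriptase template extending 10 nt of homology past the
#' edit, and edits at most 30 nt downstream of the nick. Library size is
#' capped at 60 epegRNAs and a minimum of 12 archetypal epegRNAs is
#' recommended for the pre-screen.
#'
#' @param pbs_len primer-binding-site length in nt (8-17).
#' @param rtt_3p_homology nt of post-edit homology in the RT template.
#' @param max_edit_offset maximum distance (nt) of the edit from the nick.
#' @param library_cap maximum number of epegRNAs per library.
#' @param min_archetypes recommended minimum number of archetypal epegRNAs
#'   to screen.
#' @param ngrna_offset_range allowed absolute distance (bp) between the
#'   pegRNA nick and the PE3 nicking-gRNA nick.
#' @param ngrna_offset_pref preferred absolute nick-to-nick distance (bp).
#' @param scaffold_seq,motif_seq,pool_tail_left,pool_tail_right optional
#'   overrides for the constants in [pe_constants()].
#' @return object of class `design_params`.
#' @export
design_params <- function(pbs_len = 13L,
                          rtt_3p_homology = 10L,
                          max_edit_offset = 30L,
                          library_cap = 60L,
                          min_archetypes = 12L,
                          ngrna_offset_range = c(40L, 90L),
                          ngrna_offset_pref = 60L,
                          scaffold_seq = NULL,
                          motif_seq = NULL,
                          pool_tail_left = NULL,
                          pool_tail_right = NULL) {
  const <- pe_constants()
  p <- list(
    pbs_len = as.integer(pbs_len),
    rtt_3p_homology = as.integer(rtt_3p_homology),
    max_edit_offset = as.integer(max_edit_offset),
    library_cap = as.integer(library_cap),
    min_archetypes = as.integer(min_archetypes),
    ngrna_offset_range = as.integer(ngrna_offset_range),
    ngrna_offset_pref = as.integer(ngrna_offset_pref),
    scaffold_seq = scaffold_seq %||% const$scaffold_seq,
    motif_seq = motif_seq %||% const$motif_seq,
    pool_tail_left = pool_tail_left %||% const$pool_tail_left,
    pool_tail_right = pool_tail_right %||% const$pool_tail_right,
    bsai_sites = const$bsai_sites,
    bsai_primer_ext = const$bsai_primer_ext,
    acceptor_left = const$acceptor_left,
    acceptor_right = const$acceptor_right
  )
  stopifnot(p$pbs_len >= 8L, p$pbs_len <= 17L,
            p$max_edit_offset >= p$rtt_3p_homology,
            length(p$ngrna_offset_range) == 2L,
            p$ngrna_offset_range[1] <= p$ngrna_offset_range[2])
  structure(p, class = "design_params")
}

#' Simulation configuration
#'
#' Study-condition defaults for the synthetic-data generator: a 3 kb gene
#' with 4 coding exons; a curated catalog of 40 VUS, 15 PLP, 15 BLB, 25
#' population synonymous and 10 population missense variants plus 20
#' designed premature-truncation controls; per-variant editing efficiency
#' drawn from Beta(2, 6); all-or-none variant dropout at 33%;
#' depletion-type selection with fitness 0.2 for PTC and PLP variants;
#' 300,000 read pairs per sample at 2 x 150 bp with a 0.1% per-base error
#' rate; and 3 biological replicates.
#'
#' @param seed integer seed; every draw in the generator derives from it.
#' @param gene_len approximate locus length in bp.
#' @param n_exons number of coding exons.
#' @param n_vus,n_plp,n_blb,n_pop_syn,n_pop_missense,n_ptc catalog sizes
#'   per class.
#' @param editing_shape1,editing_shape2 Beta parameters for per-variant
#'   editing efficiency.
#' @param dropout_prob probability a designed variant is absent from all
#'   pools.
#' @param fitness named per-class selection multipliers.
#' @param depth read pairs per sample.
#' @param read_len read length in bp.
#' @param error_rate per-base sequencing substitution rate.
#' @param replicates number of biological replicates.
#' @param amplicon_len amplicon length in bp (must be < 250).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       gene_len = 3000L,
                       n_exons = 4L,
                       n_vus = 40L, n_plp = 15L, n_blb = 15L,
                       n_pop_syn = 25L, n_pop_missense = 10L, n_ptc = 20L,
                       editing_shape1 = 2, editing_shape2 = 6,
                       dropout_prob = 0.33,
                       fitness = c(VUS = 1.0, PLP = 0.2, BLB = 1.0,
                                   POP_SYN = 1.0, POP_MISSENSE = 1.0,
                                   PTC_CTRL = 0.2),
                       depth = 300000L,
                       read_len = 150L,
                       error_rate = 0.001,
                       replicates = 3L,
                       amplicon_len = 240L) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, error_rate >= 0,
            error_rate <= 1, depth >= 0, amplicon_len < 250L,
            replicates >= 1L)
  structure(list(
    seed = as.integer(seed), gene_len = as.integer(gene_len),
    n_exons = as.integer(n_exons),
    n_vus = n_vus, n_plp = n_plp, n_blb = n_blb, n_pop_syn = n_pop_syn,
    n_pop_missense = n_pop_missense, n_ptc = n_ptc,
    editing_shape1 = editing_shape1, editing_shape2 = editing_shape2,
    dropout_prob = dropout_prob, fitness = fitness,
    depth = as.integer(depth), read_len = as.integer(read_len),
    error_rate = error_rate, replicates = as.integer(replicates),
    amplicon_len = as.integer(amplicon_len)
  ), class = "sim_config")
}
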