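#' Simulate codon sequence pairs with tunable nonsynonymous acceptance
#'
#' For each pair, a stop-free ancestral codon sequence is drawn and
#' mutated independently along two lineages. Proposed single-nucleotide
#' changes are uniform over the alternative bases; a proposal creating a
#' stop codon is rejected, a synonymous proposal is always accepted, and a
#' nonsynonymous proposal is accepted with probability `omega`. The
#' realized NG86 dN/dS therefore increases with `omega` and approaches 1
#' in the neutral limit `omega = 1`.
#'
#' @param pairs Data.frame with `gene_a`, `gene_b` naming the two lineage
#'   sequences of each pair.
#' @param omega Numeric vector in (0, 1], one nonsynonymous acceptance
#'   probability per pair (recycled if scalar).
#' @param n_codons Codons per sequence (>= 30).
#' @param mutation_rate Expected number of proposed single-nucleotide
#'   changes per codon, per lineage.
#' @param seed Integer seed.
#' @return A data.frame: `id_a`, `id_b`, `omega`, `seq_a`, `seq_b`.
#' @export
simulate_codon_pairs <- function(pairs, omega, n_codons = 200,
                                 mutation_rate = 0.6, seed = 1) {
  omega <- rep_len(omega, nrow(pairs))
  if (any(omega <= 0 | omega > 1))
    stop("invalid config: 'omega' must lie in (0, 1]")
  if (n_codons < 30)
    stop("invalid config: 'n_codons' must be >= 30")
  if (mutation_rate < 0)
    stop("invalid config: 'mutation_rate' must be >= 0")
  old_seed <- .GlobalEnv$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  sense_codons <- setdiff(names(genetic_code()), stop_codons())
  bases <- c("A", "C", "G", "T")
  gc <- genetic_code()
  mutate_lineage <- function(chars, w) {
    n_prop <- rpois(1, mutation_rate * length(chars) / 3)
    for (i in seq_len(n_prop)) {
      pos <- sample.int(length(chars), 1)
      new_base <- sample(setdiff(bases, chars[pos]), 1)
      cod0 <- (pos - 1) %/% 3
      codon <- chars[cod0 * 3 + 1:3]
      alt <- codon
      alt[(pos - 1) %% 3 + 1] <- new_base
      aa_old <- gc[[paste(codon, collapse = "")]]
      aa_new <- gc[[paste(alt, collapse = "")]]
      if (aa_new == "*") next                 # stop proposals rejected
      if (aa_new == aa_old || runif(1) < w)
        chars[pos] <- new_base
    }
    chars
  }
  out <- pairs[, c("gene_a", "gene_b"), drop = FALSE]
  names(out) <- c("id_a", "id_b")
  out$omega <- omega
  out$seq_a <- out$seq_b <- NA_character_
  for (p in seq_len(nrow(pairs))) {
    anc <- strsplit(paste(sample(sense_codons, n_codons, replace = TRUE),
                          collapse = ""), "")[[1]]
    out$seq_a[p] <- paste(mutate_lineage(anc, omega[p]), collapse = "")
    out$seq_b[p] <- paste(mutate_lineage(anc, omega[p]), collapse = "")
  }
  out
}

#' Write simulated sequences as FASTA
#'
#' @param codon_pairs A [simulate_codon_pairs()] result.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_codon_fasta <- function(codon_pairs, path) {
  seqs <- Biostrings::DNAStringSet(
    setNames(c(codon_pairs$seq_a, codon_pairs$seq_b),
             c(codon_pairs$id_a, codon_pairs$id_b)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the full synthetic input bundle
#'
#' Writes every input the analysis pipeline reads: the MatrixMarket
#' count bundle (10x gene x cell orientation), cluster labels, the pair
#' TSV, the gene-term annotation TSV, and (when sequences are supplied)
#' the aligned-coding-sequence FASTA. Round-trips losslessly through the
#' package readers.
#'
#' @param dir_path Output directory (created if needed).
#' @param atlas A [simulate_atlas()] result.
#' @param sequences Optional [simulate_codon_pairs()] result.
#' @return Named character vector: the file manifest.
#' @export
write_fixture_bundle <- function(dir_path, atlas, sequences = NULL) {
  stopifnot(inherits(atlas, "sim_atlas"))
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", dir_path))
  pth <- function(f) file.path(dir_path, f)
  write_mtx_bundle(atlas$matrix, pth("matrix.mtx"), pth("barcodes.tsv"),
                   pth("features.tsv"))
  write_cluster_labels(atlas$clusters, pth("labels.tsv"))
  write_gene_pairs(atlas$truth$pairs, pth("pairs.tsv"))
  write_annotation(atlas$truth$annotation, pth("annotation.tsv"))
  manifest <- c(matrix = pth("matrix.mtx"), barcodes = pth("barcodes.tsv"),
                features = pth("features.tsv"), labels = pth("labels.tsv"),
                pairs = pth("pairs.tsv"),
                annotation = pth("annotation.tsv"))
  if (!is.null(sequences)) {
    write_codon_fasta(sequences, pth("sequences.fasta"))
    manifest <- c(manifest, fasta = pth("sequences.fasta"))
  }
  manifest
}
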