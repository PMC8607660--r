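# Nei-Gojobori (1986) dN/dS estimation for aligned coding sequences.
#
# Sites: each codon position contributes (synonymous one-base changes)/3
# synonymous sites; changes creating stop codons count as nonsynonymous.
# Differences: multi-hit codons are averaged over all orderings of single
# steps, excluding orderings that pass through a stop codon (unless all
# do). Distances use the Jukes-Cantor correction d = -3/4 ln(1 - 4p/3).

.ng86_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.ng86_env$gc)) .ng86_env$gc <- Biostrings::GENETIC_CODE
  .ng86_env$gc
}

stop_codons <- function() names(genetic_code())[genetic_code() == "*"]

# per-codon synonymous site counts, computed once by neighbor enumeration
syn_site_table <- function() {
  if (!is.null(.ng86_env$syn)) return(.ng86_env$syn)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  syn <- setNames(numeric(length(gc)), names(gc))
  for (codon in names(gc)) {
    if (gc[[codon]] == "*") { syn[codon] <- NA_real_; next }
    s <- 0
    cs <- strsplit(codon, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, cs[pos])) {
      alt <- cs; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      # changes to stop codons are counted as nonsynonymous
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
    syn[codon] <- s
  }
  .ng86_env$syn <- syn
  syn
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0)
    stop("sequence length must be divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

validate_codons <- function(codons, id = "sequence") {
  known <- !is.na(match(codons, names(genetic_code())))
  internal_stop <- codons %in% stop_codons()
  if (any(internal_stop[-length(internal_stop)]))
    stop(sprintf("%s: internal stop codon at codon %d", id,
                 which(internal_stop)[1]))
  known
}

#' Construct an aligned codon sequence pair
#'
#' Normalizes case, strips alignment columns where either sequence has a
#' gap (with a message when any are removed), drops a shared terminal stop
#' codon if present, and validates frame and internal stops.
#'
#' @param id_a,id_b Sequence identifiers.
#' @param seq_a,seq_b Equal-length nucleotide strings over A/C/G/T
#'   (IUPAC ambiguity codes are tolerated; affected codons are skipped in
#'   counting), optionally containing `-` gaps at matched columns.
#' @return An object of class `codon_pair`.
#' @export
codon_pair <- function(id_a, id_b, seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop(sprintf("%s/%s: aligned sequences must have equal length",
                 id_a, id_b))
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  gap <- a == "-" | b == "-"
  if (any(gap)) {
    message(sprintf("%s/%s: stripping %d gap column(s)", id_a, id_b,
                    sum(gap)))
    a <- a[!gap]; b <- b[!gap]
  }
  seq_a <- paste(a, collapse = ""); seq_b <- paste(b, collapse = "")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (length(ca) &&
      ca[length(ca)] %in% stop_codons() &&
      cb[length(cb)] %in% stop_codons()) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  validate_codons(ca, id_a); validate_codons(cb, id_b)
  structure(list(id_a = id_a, id_b = id_b, codons_a = ca, codons_b = cb),
            class = "codon_pair")
}

#' NG86 synonymous and nonsynonymous site counts
#'
#' @param seq A nucleotide string (length divisible by 3, no internal
#'   stops) or a character vector of codons.
#' @return Named numeric vector `c(N = ..., S = ...)`; `N + S` equals the
#'   counted sequence length. Codons with ambiguous bases are skipped
#'   (with a message).
#' @export
ng86_sites <- function(seq) {
  codons <- if (length(seq) == 1 && nchar(seq[1]) > 3) split_codons(seq)
            else toupper(seq)
  known <- validate_codons(codons)
  if (any(!known))
    message(sprintf("skipping %d codon(s) with ambiguous bases",
                    sum(!known)))
  codons <- codons[known]
  codons <- codons[!codons %in% stop_codons()]  # unpaired terminal stop
  s <- sum(syn_site_table()[codons])
  c(N = 3 * length(codons) - s, S = s)
}

# classify one mutational step codon1 -> codon2 as synonymous (TRUE) or
# nonsynonymous (FALSE); steps involving a stop translation count as
# nonsynonymous
step_is_syn <- function(c1, c2) {
  gc <- genetic_code()
  a1 <- gc[[c1]]; a2 <- gc[[c2]]
  a1 != "*" && a2 != "*" && a1 == a2
}

# pathway-averaged (Nd, Sd) for a single codon pair
codon_differences <- function(c1, c2) {
  if (c1 == c2) return(c(Nd = 0, Sd = 0))
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(s1 != s2)
  orders <- if (length(diff_pos) == 1) list(diff_pos)
            else apply(perms(length(diff_pos)), 1,
                       function(o) diff_pos[o], simplify = FALSE)
  path_nd <- numeric(0); path_sd <- numeric(0); path_ok <- logical(0)
  for (ord in orders) {
    cur <- s1; nd <- 0; sd_ <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- s2[pos]
      cod1 <- paste(cur, collapse = ""); cod2 <- paste(nxt, collapse = "")
      if (genetic_code()[[cod2]] == "*" && !identical(cod2, c2)) ok <- FALSE
      if (step_is_syn(cod1, cod2)) sd_ <- sd_ + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_nd <- c(path_nd, nd); path_sd <- c(path_sd, sd_)
    path_ok <- c(path_ok, ok)
  }
  use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_nd))
  c(Nd = mean(path_nd[use]), Sd = mean(path_sd[use]))
}

perms <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' NG86 nonsynonymous and synonymous difference counts
#'
#' @param pair A [codon_pair()].
#' @return Named numeric vector `c(Nd = ..., Sd = ...)`, pathway-averaged
#'   over orderings for multi-hit codons. Codon positions where either
#'   sequence has an ambiguous base are skipped (with a message).
#' @export
ng86_differences <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  known <- validate_codons(pair$codons_a, pair$id_a) &
    validate_codons(pair$codons_b, pair$id_b)
  if (any(!known))
    message(sprintf("skipping %d codon position(s) with ambiguous bases",
                    sum(!known)))
  tot <- c(Nd = 0, Sd = 0)
  for (i in which(known))
    tot <- tot + codon_differences(pair$codons_a[i], pair$codons_b[i])
  tot
}

#' NG86 divergence estimate with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; proportions are
#' corrected with `d = -3/4 ln(1 - 4p/3)`. When a proportion reaches 0.75
#' the correction is undefined and the estimate is flagged saturated (the
#' raw proportions remain reported). The ratio is `NA` (not 0 or Inf)
#' when `dS = 0` or saturated.
#'
#' @param pair A [codon_pair()].
#' @return A one-row data.frame: `id_a`, `id_b`, `N`, `S`, `Nd`, `Sd`,
#'   `pN`, `pS`, `dN`, `dS`, `dnds_ratio`, `saturated`.
#' @export
divergence <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  sa <- ng86_sites(pair$codons_a)
  sb <- ng86_sites(pair$codons_b)
  N <- (sa["N"] + sb["N"]) / 2
  S <- (sa["S"] + sb["S"]) / 2
  d <- ng86_differences(pair)
  pN <- if (N > 0) unname(d["Nd"] / N) else 0
  pS <- if (S > 0) unname(d["Sd"] / S) else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  dN <- jc(pN); dS <- jc(pS)
  saturated <- is.na(dN) || is.na(dS)
  ratio <- if (!saturated && dS > 0) dN / dS else NA_real_
  data.frame(id_a = pair$id_a, id_b = pair$id_b,
             N = unname(N), S = unname(S),
             Nd = unname(d["Nd"]), Sd = unname(d["Sd"]),
             pN = pN, pS = pS, dN = dN, dS = dS,
             dnds_ratio = ratio, saturated = saturated,
             stringsAsFactors = FALSE)
}

#' Estimate divergence for all pairs in a FASTA
#'
#' Reads aligned coding sequences with `Biostrings::readDNAStringSet()`
#' and computes [divergence()] for each pair listed in the pair table,
#' matching records by id.
#'
#' @param fasta_path FASTA of aligned coding sequences.
#' @param pairs Data.frame with `gene_a`, `gene_b` naming FASTA records.
#' @return A data.frame of [divergence()] rows, one per pair.
#' @export
divergence_table <- function(fasta_path, pairs) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), ids)
  if (length(missing))
    stop(sprintf("sequence '%s' missing from %s", missing[1], fasta_path))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    divergence(codon_pair(a, b, as.character(seqs[[a]]),
                          as.character(seqs[[b]])))
  }))
}
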