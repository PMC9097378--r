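#' Globally align an LTR pair
#'
#' Needleman-Wunsch alignment (match +1, mismatch -1, gap open 5, gap
#' extend 1) of the 5' and 3' LTR of one locus. Columns containing a gap or
#' an N are excluded from substitution counting; the remainder yield the
#' transition proportion P (A<->G, C<->T) and transversion proportion Q.
#'
#' @param ltr5,ltr3 Uppercase DNA strings (A/C/G/T/N).
#' @return `list` with `aligned_length` (columns compared), `P`, `Q`.
#' @export
align_ltr_pair <- function(ltr5, ltr3) {
  ltr5 <- as.character(ltr5); ltr3 <- as.character(ltr3)
  if (nchar(ltr5) == 0L || nchar(ltr3) == 0L)
    stop("empty LTR sequence")
  if (grepl("[^ACGTN]", ltr5) || grepl("[^ACGTN]", ltr3))
    stop("LTR sequences must contain only A, C, G, T or N")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    ltr5, ltr3, type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) return(list(aligned_length = 0L, P = NA_real_, Q = NA_real_))
  diff <- a != b
  transition <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                          (a %in% c("C", "T") & b %in% c("C", "T")))
  list(aligned_length = n,
       P = sum(transition) / n,
       Q = sum(diff & !transition) / n)
}

#' Kimura two-parameter distance
#'
#' \eqn{K = -\frac{1}{2}\ln[(1 - 2P - Q)\sqrt{1 - 2Q}]} from transition and
#' transversion proportions. Saturated pairs (where the logarithm's argument
#' is not positive) raise an error of class `"teloci_saturation"`; callers
#' flag and exclude such loci from dating.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("teloci_saturation", "error", "condition"),
                   list(message = sprintf(
                     "saturated divergence (P=%.3f, Q=%.3f)", P, Q),
                     call = sys.call(-1))))
  -0.5 * log(w1 * sqrt(w2))
}

#' Insertion time from LTR divergence
#'
#' \eqn{T = K / (2 r)}, reported in million years (MYA): identical LTRs at
#' insertion diverge on both copies at rate `r` per site per year.
#'
#' @param K Kimura two-parameter distance.
#' @param r Substitution rate per site per year.
#' @return Time in MYA.
#' @export
insertion_time <- function(K, r = 1.3e-8) {
  stopifnot(all(K >= 0), r > 0)
  K / (2 * r) / 1e6
}

#' Date all structurally intact LTR loci of an annotation
#'
#' Extracts both LTR sub-features of every locus that has them, aligns the
#' pair and converts divergence into an insertion time. Saturated pairs are
#' kept in the table with `saturated = TRUE` and `K`/`T` set to `NA`.
#'
#' @param te TE `GRanges` with LTR5/LTR3 sub-features in
#'   `metadata(te)$sub_features`.
#' @param genome `DNAStringSet` named by chromosome.
#' @param config [analysis_config()] (supplies the substitution rate).
#' @return `data.frame` with `locus_id`, `family`, `aligned_length`, `P`,
#'   `Q`, `K`, `T_mya`, `saturated`.
#' @export
date_ltr_loci <- function(te, genome, config = analysis_config()) {
  sfg <- S4Vectors::metadata(te)$sub_features
  if (is.null(sfg)) stop("annotation carries no structural sub-features")
  ids <- intersect(sfg$locus_id[sfg$feature_type == "LTR5"],
                   sfg$locus_id[sfg$feature_type == "LTR3"])
  rows <- lapply(ids, function(id) {
    l5 <- sfg[sfg$locus_id == id & sfg$feature_type == "LTR5"][1]
    l3 <- sfg[sfg$locus_id == id & sfg$feature_type == "LTR3"][1]
    get_seq <- function(x) as.character(Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(x))]],
      GenomicRanges::start(x), GenomicRanges::end(x)))
    pq <- align_ltr_pair(get_seq(l5), get_seq(l3))
    K <- tryCatch(k2p_distance(pq$P, pq$Q),
                  teloci_saturation = function(e) NA_real_)
    data.frame(locus_id = id,
               family = te$family[match(id, te$locus_id)],
               aligned_length = pq$aligned_length,
               P = pq$P, Q = pq$Q, K = K,
               T_mya = if (is.na(K)) NA_real_
                       else insertion_time(K, config$substitution_rate),
               saturated = is.na(K))
  })
  do.call(rbind, rows)
}

#' Peak (mode) of an insertion-time distribution
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a 512-point grid over [0, max(times)]; the peak is the grid
#' argmax (ties resolved to the smallest time).
#'
#' @param times Insertion times in MYA (at least 10 values).
#' @return Peak time in MYA.
#' @export
peak_insertion_time <- function(times) {
  times <- times[!is.na(times)]
  if (length(times) < 10L)
    stop("need at least 10 insertion times for a peak estimate")
  if (max(times) == min(times)) return(times[1])
  d <- stats::density(times, bw = "nrd0", from = 0, to = max(times),
                      n = 512)
  d$x[which.max(d$y)]
}

#' Per-family insertion-age profiles
#'
#' Summarises [date_ltr_loci()] output into amplification-peak estimates
#' for families with at least `min_loci` datable (non-saturated) loci;
#' smaller families are skipped with a message.
#'
#' @param dating Output of [date_ltr_loci()].
#' @param min_loci Minimum datable loci per family (default 10).
#' @return `data.frame` with `family`, `n_loci`, `peak_time_mya`,
#'   `mean_time_mya`.
#' @export
family_age_profiles <- function(dating, min_loci = 10) {
  ok <- dating[!dating$saturated, , drop = FALSE]
  fams <- split(ok$T_mya, ok$family)
  small <- names(fams)[vapply(fams, length, integer(1)) < min_loci]
  if (length(small) > 0L)
    message("skipping families with < ", min_loci, " dated loci: ",
            paste(small, collapse = ", "))
  fams <- fams[vapply(fams, length, integer(1)) >= min_loci]
  if (length(fams) == 0L)
    return(data.frame(family = character(), n_loci = integer(),
                      peak_time_mya = numeric(), mean_time_mya = numeric()))
  data.frame(family = names(fams),
             n_loci = vapply(fams, length, integer(1)),
             peak_time_mya = vapply(fams, peak_insertion_time, numeric(1)),
             mean_time_mya = vapply(fams, mean, numeric(1)),
             row.names = NULL)
}
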