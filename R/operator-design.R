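#' The constitutive synRNAP-s70 promoter sequence
#'
#' The 47-nt synthetic sigma-70 promoter used as the scaffold of every
#' repression reporter: the transcription-factor operator is cloned
#' immediately downstream of its -10 element, so factor binding represses
#' an otherwise constitutive output.
#'
#' @return A single character string (47 nt).
#' @export
syn_rnap_s70_promoter <- function() {
  "AATAATTCTTGAAATTTATGCTTCCGGCTCGTATTTTACGTGCAATT"
}

# Base set of each IUPAC code, from Biostrings; inverted lookup for the
# minimal covering code.
iupac_sets <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(s) strsplit(s, "")[[1]])
}

code_for_bases <- function(bases) {
  sets <- iupac_sets()
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(sets)[vapply(sets, function(s)
    identical(paste(sort(s), collapse = ""), key), logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for base set {",
                              paste(bases, collapse = ","), "}")
  hit
}

check_iupac <- function(seq, gaps = FALSE) {
  alphabet <- names(Biostrings::IUPAC_CODE_MAP)
  if (gaps) alphabet <- c(alphabet, "-")
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(ch), alphabet)
  if (length(bad))
    stop("invalid character(s) for IUPAC DNA: ",
         paste(shQuote(bad), collapse = ", "))
  ch
}

#' Degenerate IUPAC consensus of aligned binding sites
#'
#' Column-wise consensus of an alignment of operator sites: each column
#' is encoded as the minimal IUPAC code covering the bases observed
#' there. With `purity_threshold = 0` (default) every observed base is
#' covered, yielding a fully degenerate consensus suitable for library
#' primers; raising the threshold drops bases rarer than that fraction
#' of the (non-gap) column, giving a majority-style consensus. Gaps are
#' ignored for code selection; an all-gap column is an error.
#'
#' @param sites character vector (or `Biostrings::DNAStringSet`) of
#'   `>= 2` aligned, equal-length sequences over `A`, `C`, `G`, `T`,
#'   `-`.
#' @param purity_threshold minimum within-column frequency for a base to
#'   be covered (default 0 = cover all observed bases).
#' @return IUPAC consensus string, same length as the alignment.
#' @export
#' @examples
#' iupac_consensus(c("ACGT", "ACGA"))  # "ACGW"
iupac_consensus <- function(sites, purity_threshold = 0) {
  if (inherits(sites, "DNAStringSet")) sites <- as.character(sites)
  stopifnot(is.character(sites), length(sites) >= 2L,
            purity_threshold >= 0, purity_threshold < 1)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L)
    stop("aligned sites must have equal lengths")
  mat <- do.call(rbind, lapply(sites, check_iupac, gaps = TRUE))
  if (any(!mat %in% c("A", "C", "G", "T", "-")))
    stop("alignment columns must contain only A, C, G, T or '-'")
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) stop("column ", j, " contains only gaps")
    freq <- table(col) / length(col)
    keep <- names(freq)[freq > 0 & freq >= purity_threshold]
    if (length(keep) == 0L) keep <- names(freq)[which.max(freq)]
    code_for_bases(keep)
  }, character(1))
  paste(cons, collapse = "")
}

#' Number of distinct sequences encoded by a degenerate oligo
#'
#' Product over positions of each IUPAC code's base multiplicity: a
#' fully specified oligo encodes 1 sequence, every `N` multiplies the
#' library size by 4.
#'
#' @param seq IUPAC DNA string.
#' @return Integer-valued count (as numeric, since libraries can exceed
#'   `.Machine$integer.max`).
#' @export
#' @examples
#' count_degenerate_variants("ACGT")  # 1
#' count_degenerate_variants("NN")    # 16
count_degenerate_variants <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  ch <- check_iupac(seq)
  prod(vapply(iupac_sets()[ch], length, integer(1)))
}

#' Assemble a repression-reporter sequence
#'
#' Places an operator immediately downstream of the constitutive
#' promoter; the returned construct records the junction coordinate
#' (1-based: promoter length + 1) and the size of the degenerate library
#' the operator encodes.
#'
#' @param operator operator sequence; IUPAC degeneracy codes allowed.
#' @param promoter promoter sequence (default the synRNAP-s70 promoter,
#'   [syn_rnap_s70_promoter()]).
#' @return An object of class `reporter_construct`: `promoter_seq`,
#'   `operator_seq`, `full_seq`, `junction` (1-based position of the
#'   operator's first base), `n_variants`.
#' @export
#' @examples
#' build_reporter_sequence("ACGT")$junction  # 48
build_reporter_sequence <- function(operator,
                                    promoter = syn_rnap_s70_promoter()) {
  stopifnot(is.character(operator), length(operator) == 1L,
            is.character(promoter), length(promoter) == 1L)
  if (!nzchar(operator)) stop("empty operator sequence")
  if (!nzchar(promoter)) stop("empty promoter sequence")
  check_iupac(operator); check_iupac(promoter)
  promoter <- toupper(promoter); operator <- toupper(operator)
  structure(list(promoter_seq = promoter, operator_seq = operator,
                 full_seq = paste0(promoter, operator),
                 junction = nchar(promoter) + 1L,
                 n_variants = count_degenerate_variants(operator)),
            class = "reporter_construct")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("Repression-reporter construct\n")
  cat("  promoter (", nchar(x$promoter_seq), " nt): ", x$promoter_seq,
      "\n", sep = "")
  cat("  operator (", nchar(x$operator_seq), " nt): ", x$operator_seq,
      "\n", sep = "")
  cat("  operator junction at position ", x$junction,
      " (1-based); library size ", x$n_variants, "\n", sep = "")
  invisible(x)
}

#' Cloning and reporter-design primers
#'
#' The primer set used to amplify the four promoter regions and to build
#' the degenerate operator libraries (verbatim printed sequences,
#' including their degenerate positions), shipped as a FASTA file.
#'
#' @return Named character vector of primer sequences.
#' @export
reporter_primers <- function() {
  path <- system.file("extdata", "reporter_primers.fasta",
                      package = "araLogic", mustWork = TRUE)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Read / write DNA FASTA
#'
#' Thin wrappers over `Biostrings` for the module's FASTA interface.
#'
#' @param path file path.
#' @param seqs named character vector of sequences (for writing).
#' @return `read_fasta`: named character vector; `write_fasta`:
#'   `path`, invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
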