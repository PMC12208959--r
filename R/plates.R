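# License-plate codec: a reversible base-32 naming scheme for small RNA
# sequences.  A plate renders as "<prefix>-<length>-<payload>" where the
# payload encodes the nucleotide sequence itself, so labels are unique,
# assembly-agnostic and require no central registry.

#' The 32-symbol plate alphabet
#'
#' The ten digits and the capital letters of the English alphabet except
#' A, C, G and T (which would be mistaken for nucleotides), interleaved
#' two letters / one digit with letters in alphabetical and digits in
#' numeric order.
#'
#' @format A length-32 character vector; position \code{i} holds the symbol
#'   for value \code{i - 1}.
#' @export
plate_alphabet <- strsplit("BD0EF1HI2JK3LM4NO5PQ6RS7UV8WX9YZ", "")[[1]]

.plate_nucs <- c("A", "C", "G", "T")

# Two 4-mer codes are pinned by published labels and provably deviate from
# the plain positional rule; the codec swaps these chunk pairs (an
# involution, so bijectivity is preserved).
.plate_4mer_swaps <- c(GAGC = "TCTC", TCTC = "GAGC", CTGC = "TATC", TATC = "CTGC")

# chunk <-> code lookup tables per chunk length, built once at load
.plate_tables <- new.env(parent = emptyenv())

.plate_build_tables <- function() {
  for (len in 1:5) {
    n <- 4L^len
    v <- 0L:(n - 1L)
    digits <- matrix(0L, nrow = n, ncol = len)
    tmp <- v
    for (pos in len:1) {
      digits[, pos] <- tmp %% 4L
      tmp <- tmp %/% 4L
    }
    chunks <- apply(digits, 1L, function(d) paste(.plate_nucs[d + 1L], collapse = ""))
    if (len <= 2L) {
      codes <- plate_alphabet[v + 1L]
    } else {
      codes <- paste0(plate_alphabet[v %/% 32L + 1L], plate_alphabet[v %% 32L + 1L])
    }
    names(codes) <- chunks
    if (len == 4L) {
      swapped <- codes
      swapped[names(.plate_4mer_swaps)] <- codes[unname(.plate_4mer_swaps)]
      codes <- swapped
    }
    inv <- names(codes)
    names(inv) <- unname(codes)
    assign(paste0("enc", len), codes, envir = .plate_tables)
    assign(paste0("dec", len), inv, envir = .plate_tables)
  }
}
.plate_build_tables()

.plate_prefixes <- c("iso", "tRF", "rRF", "yRF", "na")

.check_acgt <- function(seq) {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop("invalid-sequence: non-ACGT character in ",
         paste(utils::head(seq[bad], 3L), collapse = ", "), call. = FALSE)
  }
}

#' Encode one nucleotide chunk (1-5 nt) as its plate code
#'
#' A length-5 chunk maps to the big-endian base-4 value
#' \eqn{v = \sum_i d_i 4^{5-i}} (A=0, C=1, G=2, T=3, read 5' to 3') and is
#' written as the two symbols \code{alphabet[v div 32], alphabet[v mod 32]};
#' chunks of length 1-2 fit in a single symbol.  The mapping is injective
#' within each chunk length.
#'
#' @param chunk A character vector of A/C/G/T strings, each 1-5 nt.
#' @return A character vector of 1- or 2-symbol codes.
#' @examples
#' encode_chunk("GGGGG")  # "RK"
#' encode_chunk("AAAAA")  # "BB"
#' @export
encode_chunk <- function(chunk) {
  if (length(chunk) == 0L) return(character(0))
  if (any(!nzchar(chunk))) stop("invalid-argument: empty chunk", call. = FALSE)
  .check_acgt(chunk)
  len <- nchar(chunk)
  if (any(len > 5L)) stop("invalid-argument: chunk longer than 5 nt", call. = FALSE)
  out <- character(length(chunk))
  for (l in unique(len)) {
    tab <- get(paste0("enc", l), envir = .plate_tables)
    out[len == l] <- unname(tab[chunk[len == l]])
  }
  out
}

#' Payload character count implied by a sequence length
#'
#' Full 5-nt chunks cost two symbols each; a trailing remainder of 1-2 nt
#' costs one symbol and of 3-4 nt costs two.
#'
#' @param L Integer vector of sequence lengths (nt), all >= 1.
#' @return Integer vector of payload lengths.
#' @examples
#' payload_length(24)  # 10, as in tRF-24-RK9P4P9LH9
#' @export
payload_length <- function(L) {
  L <- as.integer(L)
  if (any(is.na(L)) || any(L < 1L)) stop("invalid-argument: L must be >= 1", call. = FALSE)
  2L * (L %/% 5L) + c(0L, 1L, 1L, 2L, 2L)[L %% 5L + 1L]
}

.plate_chunk_starts <- function(L) {
  # trailing remainder: full 5-mers first, short chunk (if any) last
  n_full <- L %/% 5L
  r <- L %% 5L
  starts <- if (n_full > 0L) seq.int(1L, by = 5L, length.out = n_full) else integer(0)
  widths <- rep(5L, n_full)
  if (r > 0L) {
    starts <- c(starts, n_full * 5L + 1L)
    widths <- c(widths, r)
  }
  list(starts = starts, widths = widths)
}

#' Encode a nucleotide sequence as a rendered license plate
#'
#' The sequence is split 5' to 3' into 5-nt chunks with a trailing
#' remainder, each chunk is encoded with \code{\link{encode_chunk}}, and the
#' concatenated payload is rendered as \code{"<prefix>-<length>-<payload>"}.
#' The payload depends only on the sequence, never on the prefix.
#'
#' @param seq Character vector of A/C/G/T sequences (length >= 1 nt each).
#' @param prefix One of \code{"iso"}, \code{"tRF"}, \code{"rRF"},
#'   \code{"yRF"}, \code{"na"}; recycled across \code{seq}.
#' @return Character vector of rendered plates.
#' @examples
#' plate_encode("GGGGGTGTAGCTCAGTGGTAGAGC", "tRF")  # "tRF-24-RK9P4P9LH9"
#' @export
plate_encode <- function(seq, prefix = "na") {
  if (length(seq) == 0L) return(character(0))
  prefix <- rep_len(as.character(prefix), length(seq))
  if (!all(prefix %in% .plate_prefixes)) {
    stop("invalid-argument: prefix must be one of ",
         paste(.plate_prefixes, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seq))) stop("invalid-sequence: empty sequence", call. = FALSE)
  .check_acgt(seq)
  vapply(seq_along(seq), function(i) {
    s <- seq[[i]]
    L <- nchar(s)
    cs <- .plate_chunk_starts(L)
    chunks <- substring(s, cs$starts, cs$starts + cs$widths - 1L)
    paste0(prefix[[i]], "-", L, "-", paste(encode_chunk(chunks), collapse = ""))
  }, character(1))
}

#' Parse a rendered plate into its prefix, length and payload fields
#'
#' @param plate Character vector of rendered plates.
#' @return A data.frame with columns \code{prefix}, \code{length},
#'   \code{payload}.
#' @export
plate_parse <- function(plate) {
  m <- regmatches(plate, regexec("^(iso|tRF|rRF|yRF|na)-([0-9]+)-([0-9A-Z]+)$", plate))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed-plate: ", paste(utils::head(plate[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    prefix  = vapply(m, `[[`, character(1), 2L),
    length  = as.integer(vapply(m, `[[`, character(1), 3L)),
    payload = vapply(m, `[[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

#' Decode a rendered license plate back to its nucleotide sequence
#'
#' The length field determines the chunking, so
#' \code{plate_decode(plate_encode(s)) == s} for every valid sequence.
#'
#' @param plate Character vector of rendered plates.
#' @return Character vector of A/C/G/T sequences.
#' @examples
#' plate_decode("tRF-24-RK9P4P9LH9")
#' @export
plate_decode <- function(plate) {
  if (length(plate) == 0L) return(character(0))
  fields <- plate_parse(plate)
  vapply(seq_len(nrow(fields)), function(i) {
    L <- fields$length[[i]]
    payload <- fields$payload[[i]]
    if (nchar(payload) != payload_length(L)) {
      stop("malformed-plate: payload has ", nchar(payload),
           " characters but length ", L, " requires ", payload_length(L),
           call. = FALSE)
    }
    cs <- .plate_chunk_starts(L)
    pos <- 1L
    out <- character(length(cs$widths))
    for (k in seq_along(cs$widths)) {
      w <- cs$widths[[k]]
      nsym <- if (w <= 2L) 1L else 2L
      code <- substr(payload, pos, pos + nsym - 1L)
      pos <- pos + nsym
      tab <- get(paste0("dec", w), envir = .plate_tables)
      chunk <- tab[code]
      if (is.na(chunk)) {
        stop("malformed-plate: code '", code, "' has no preimage at chunk length ",
             w, call. = FALSE)
      }
      out[[k]] <- unname(chunk)
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Expected chance occurrences of a k-mer in a genome
#'
#' For a sequence of length \code{L} searched on both strands of a genome of
#' \code{genome_size} bases, the expected number of exact occurrences under
#' a uniform base model is \code{strands * genome_size * 4^-L}.  Used to
#' judge whether a short unannotated fragment's genomic placement is
#' surprising (e.g. a 15-mer in a 3.1 Gb genome is expected about 5.8 times
#' by chance).
#'
#' @param L Sequence length in nt.
#' @param genome_size Genome size in bases (default human, 3.1e9).
#' @param strands Number of strands searched (default 2).
#' @return Numeric expected occurrence count.
#' @export
expected_genome_occurrences <- function(L, genome_size = 3.1e9, strands = 2) {
  if (any(L < 1)) stop("invalid-argument: L must be >= 1", call. = FALSE)
  strands * genome_size * 4^(-L)
}
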