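#' @useDynLib dhlppi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head combn read.table write.table
NULL

# Fixed integer codes for the 20 standard amino acids. Token 0 is reserved
# for padding; every residue gets a code in 1..20.
AA_CODES <- c(
  A = 1L, G = 2L, V = 3L, I = 4L, L = 5L, F = 6L, P = 7L, Y = 8L, M = 9L,
  T = 10L, S = 11L, H = 12L, N = 13L, Q = 14L, W = 15L, R = 16L, K = 17L,
  D = 18L, E = 19L, C = 20L
)

#' Read a protein FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file via
#' [Biostrings::readAAStringSet()]. The identifier of each record is the
#' header token before the first whitespace; identifiers must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named list of records; each record is a list with elements
#'   `id` and `sequence`. Order of the file is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # fail early, with the line, on sequence data appearing before any header
  probe <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(probe)))
  if (length(nonblank) && !startsWith(probe[nonblank[1L]], ">")) {
    stop("malformed FASTA: line ", nonblank[1L],
         " is sequence data before any '>' header")
  }
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aas) == 0L) return(list())
  ids <- vapply(names(aas), function(h) strsplit(h, "[ \t]")[[1L]][1L],
                character(1), USE.NAMES = FALSE)
  if (any(is.na(ids) | !nzchar(ids))) stop("malformed FASTA: empty identifier")
  dup <- anyDuplicated(ids)
  if (dup) stop("duplicate FASTA id: '", ids[dup], "'")
  recs <- Map(function(id, s) list(id = id, sequence = toupper(s)),
              ids, as.character(aas))
  names(recs) <- ids
  recs
}

#' Convert a protein sequence to a fixed-length integer token sequence
#'
#' Each residue is mapped to its fixed integer code (A=1, G=2, ..., C=20);
#' the result is zero-padded to length `L`. Sequences longer than `L` are
#' truncated to their first `L` residues (with a warning).
#'
#' @param sequence Character scalar: the amino-acid sequence (or a record as
#'   returned by [read_fasta()]).
#' @param L Padded length (positive integer; the network input width).
#' @param pad_side `"trailing"` (default) or `"leading"`: where the zeros go.
#' @param strict If `TRUE`, a residue outside the 20-letter alphabet is an
#'   error; otherwise it is mapped to the padding token 0 with a warning.
#' @return Integer vector of length `L` with values in 0..20.
#' @export
tokenize <- function(sequence, L = 5000L, pad_side = c("trailing", "leading"),
                     strict = FALSE) {
  pad_side <- match.arg(pad_side)
  if (is.list(sequence)) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) > L) {
    warning("sequence of length ", length(chars), " truncated to first ", L,
            " residues")
    chars <- chars[seq_len(L)]
  }
  toks <- unname(AA_CODES[chars])
  unknown <- is.na(toks)
  if (any(unknown)) {
    if (strict) {
      stop("non-standard residue(s) in sequence: ",
           paste(unique(chars[unknown]), collapse = ", "))
    }
    warning("non-standard residue(s) mapped to padding token 0: ",
            paste(unique(chars[unknown]), collapse = ", "))
    toks[unknown] <- 0L
  }
  pad <- integer(L - length(toks))
  if (pad_side == "trailing") c(toks, pad) else c(pad, toks)
}

#' Tokenize a list of protein records into a matrix
#'
#' @param records List of records from [read_fasta()] (or a named character
#'   vector of sequences).
#' @inheritParams tokenize
#' @return Integer matrix, one row per protein (rownames = ids), `L` columns.
#' @export
tokenize_all <- function(records, L = 5000L, pad_side = "trailing",
                         strict = FALSE) {
  if (is.character(records)) {
    ids <- names(records)
    seqs <- unname(records)
  } else {
    ids <- vapply(records, `[[`, character(1), "id")
    seqs <- vapply(records, `[[`, character(1), "sequence")
  }
  if (is.null(ids) || anyDuplicated(ids)) stop("records must carry unique ids")
  out <- matrix(0L, nrow = length(seqs), ncol = L, dimnames = list(ids, NULL))
  for (i in seq_along(seqs)) {
    out[i, ] <- tokenize(seqs[i], L = L, pad_side = pad_side, strict = strict)
  }
  out
}

#' Read a labeled protein-pair list
#'
#' Expects a headerless, three-column, tab-separated file:
#' `id_a<TAB>id_b<TAB>label`, label in \{0,1\}.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `id_a`, `id_b` (character) and
#'   `label` (integer 0/1). Zero rows for an empty file.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                   quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("pair file must have exactly 3 tab-separated columns")
  names(df) <- c("id_a", "id_b", "label")
  lab <- suppressWarnings(as.integer(df$label))
  bad <- is.na(lab) | !(lab %in% c(0L, 1L)) | df$label != as.character(lab)
  if (any(bad)) {
    stop("invalid label '", df$label[which(bad)[1L]], "' at row ", which(bad)[1L],
         ": labels must be 0 or 1")
  }
  df$label <- lab
  df
}

#' Write a labeled pair list as TSV
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs[, c("id_a", "id_b", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write protein records as FASTA
#'
#' @param records List of records (`id`, `sequence`) or named character vector.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    seqs <- records
  } else {
    seqs <- setNames(vapply(records, `[[`, character(1), "sequence"),
                     vapply(records, `[[`, character(1), "id"))
  }
  aas <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aas, path, width = width)
  invisible(path)
}

# Decode a token vector back to its residue string (padding dropped).
# Inverse of tokenize on the standard alphabet; used by tests.
detokenize <- function(tokens) {
  tokens <- tokens[tokens != 0L]
  paste0(names(AA_CODES)[tokens], collapse = "")
}
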