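DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Adds a pseudocount (spread uniformly over the four bases), column
#' normalizes to base probabilities, and converts to log2 odds against a
#' uniform background. A uniform column therefore scores 0 everywhere and
#' the consensus base of each column attains the column maximum.
#'
#' @param count_matrix 4 x L numeric matrix of non-negative base counts;
#'   rows A, C, G, T (rownames optional but honored when present).
#' @param pseudocount Total pseudocount per column; default 0.8.
#' @return Object of class `songnet_pwm`: log2-odds `weights` (4 x L),
#'   base probabilities `prob`, per-position `max`/`min`, `max_score`,
#'   `min_score`, and the `consensus` string.
#' @export
pwm_from_counts <- function(count_matrix, pseudocount = 0.8) {
  m <- as.matrix(count_matrix)
  if (nrow(m) != 4) stop("count matrix must have 4 rows (A, C, G, T)", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(colSums(m) == 0)) stop("every column needs a positive count sum", call. = FALSE)
  if (!is.null(rownames(m))) m <- m[DNA_BASES, , drop = FALSE] else rownames(m) <- DNA_BASES
  prob <- sweep(m + pseudocount / 4, 2, colSums(m) + pseudocount, "/")
  w <- log2(prob / 0.25)
  pos_max <- apply(w, 2, max)
  pos_min <- apply(w, 2, min)
  structure(list(
    weights = w,
    prob = prob,
    pos_max = pos_max,
    pos_min = pos_min,
    max_score = sum(pos_max),
    min_score = sum(pos_min),
    consensus = paste(DNA_BASES[apply(w, 2, which.max)], collapse = ""),
    pseudocount = pseudocount
  ), class = "songnet_pwm")
}

#' @export
print.songnet_pwm <- function(x, ...) {
  cat(sprintf("PWM of width %d, consensus %s (score range %.2f .. %.2f)\n",
              ncol(x$weights), x$consensus, x$min_score, x$max_score))
  invisible(x)
}

#' Read a JASPAR-format motif count matrix
#'
#' Parses the JASPAR text format (a `>` header line followed by four
#' `A [ ... ]`-style rows) into a [pwm_from_counts()] object.
#'
#' @param path Path to the JASPAR file.
#' @param pseudocount Passed to [pwm_from_counts()].
#' @return A `songnet_pwm`; the header id/name is kept as attribute
#'   `motif_id`.
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines, value = TRUE)
  rows <- grep("^>", lines, value = TRUE, invert = TRUE)
  parsed <- lapply(rows[1:4], function(l) {
    body <- sub("^\\s*[ACGTacgt]", "", l)
    as.numeric(regmatches(body, gregexpr("[0-9.]+", body))[[1]])
  })
  if (length(unique(lengths(parsed))) != 1) {
    stop("malformed JASPAR matrix: unequal row lengths", call. = FALSE)
  }
  counts <- do.call(rbind, parsed)
  rownames(counts) <- toupper(substr(trimws(rows[1:4]), 1, 1))
  pwm <- pwm_from_counts(counts, pseudocount = pseudocount)
  attr(pwm, "motif_id") <- if (length(header)) sub("^>\\s*", "", header[1]) else NA_character_
  pwm
}

# raw additive score of a single L-length window; NA if it contains a
# non-ACGT character
raw_pwm_score <- function(pwm, window) {
  idx <- match(strsplit(window, "")[[1]], DNA_BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$weights[cbind(idx, seq_along(idx))])
}

#' Relative PWM score of a sequence window
#'
#' `(score - min_score) / (max_score - min_score)`, the fraction of the
#' achievable score range, as used by the 80% hit-score convention.
#'
#' @param pwm A `songnet_pwm`.
#' @param window Character string of the motif's width.
#' @return Relative score in \[0, 1\] (`NA` for windows containing N).
#' @export
relative_pwm_score <- function(pwm, window) {
  (raw_pwm_score(pwm, window) - pwm$min_score) / (pwm$max_score - pwm$min_score)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

scan_one_strand <- function(seqv, pwm) {
  L <- ncol(pwm$weights)
  n <- nchar(seqv)
  if (n < L) return(tibble::tibble(offset = integer(), score = numeric()))
  idx <- match(strsplit(seqv, "")[[1]], DNA_BASES)
  n_win <- n - L + 1
  score <- numeric(n_win)
  bad <- logical(n_win)
  for (p in seq_len(L)) {
    b <- idx[p:(p + n_win - 1)]
    na <- is.na(b)
    bad <- bad | na
    b[na] <- 1L
    score <- score + pwm$weights[cbind(b, p)]
  }
  score[bad] <- NA_real_
  tibble::tibble(offset = seq_len(n_win) - 1L, score = score)
}

#' Scan sequences for PWM matches
#'
#' Slides the PWM over each sequence (and, by default, its reverse
#' complement) and reports windows whose relative score — the fraction of
#' the PWM's achievable score range — reaches `min_relative`. Windows
#' containing N are skipped. Offsets are 0-based forward-strand
#' coordinates of the half-open window `[offset, offset + L)`; minus
#' strand hits are mapped back to forward coordinates.
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of sequences over A, C, G, T, N.
#' @param pwm A `songnet_pwm`.
#' @param min_relative Minimum relative hit score; default 0.80.
#' @param both_strands Also scan the reverse complement? Default `TRUE`.
#' @return Tibble of hits: `seq_id`, `offset`, `strand`, `score`,
#'   `relative_score`, `match`.
#' @export
scan_pwm <- function(sequences, pwm, min_relative = 0.80, both_strands = TRUE) {
  stopifnot(inherits(pwm, "songnet_pwm"))
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  }
  L <- ncol(pwm$weights)
  rng <- pwm$max_score - pwm$min_score
  one_seq <- function(id) {
    s <- toupper(sequences[[id]])
    fwd <- scan_one_strand(s, pwm)
    fwd$strand <- "+"
    out <- fwd
    if (both_strands) {
      rc <- scan_one_strand(reverse_complement(s), pwm)
      rc$offset <- nchar(s) - L - rc$offset  # map back to forward coordinates
      rc$strand <- "-"
      out <- dplyr::bind_rows(fwd, rc)
    }
    out$relative_score <- (out$score - pwm$min_score) / rng
    hits <- out[!is.na(out$relative_score) & out$relative_score >= min_relative, ]
    if (nrow(hits) == 0) return(NULL)
    hits$seq_id <- id
    hits$match <- substr(rep(s, nrow(hits)), hits$offset + 1, hits$offset + L)
    hits
  }
  res <- dplyr::bind_rows(purrr::map(names(sequences), one_seq))
  if (nrow(res) == 0) {
    return(tibble::tibble(seq_id = character(), offset = integer(),
                          strand = character(), score = numeric(),
                          relative_score = numeric(), match = character()))
  }
  dplyr::select(res, "seq_id", "offset", "strand", "score",
                "relative_score", "match") %>%
    dplyr::arrange(.data$seq_id, .data$offset, .data$strand)
}

#' Extract promoter sequences upstream of transcription start sites
#'
#' For a plus-strand gene the promoter is the half-open interval
#' `[TSS - upstream, TSS)` (0-based); for a minus-strand gene it is the
#' reverse complement of `(TSS, TSS + upstream]`. Promoters running off a
#' contig edge are truncated with a warning.
#'
#' @param gene_table Tibble with `gene_id`, `seq_id`, `tss` (0-based
#'   coordinate), `strand` (`"+"`/`"-"`).
#' @param sequences Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param upstream Promoter length in bp; default 1000.
#' @return Named character vector of promoter sequences (one per gene).
#' @export
extract_promoters <- function(gene_table, sequences, upstream = 1000) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  out <- character(nrow(gene_table))
  names(out) <- gene_table$gene_id
  for (i in seq_len(nrow(gene_table))) {
    s <- sequences[[gene_table$seq_id[i]]]
    if (is.null(s)) stop("unknown contig: ", gene_table$seq_id[i], call. = FALSE)
    n <- nchar(s)
    tss <- gene_table$tss[i]
    if (tss < 0 || tss >= n) {
      stop("TSS outside contig for gene ", gene_table$gene_id[i], call. = FALSE)
    }
    if (gene_table$strand[i] == "+") {
      start <- tss - upstream
      if (start < 0) {
        warning("promoter truncated at contig edge for gene ", gene_table$gene_id[i])
        start <- 0
      }
      out[i] <- substr(s, start + 1, tss)  # [start, tss) in 0-based terms
    } else {
      end <- tss + upstream
      if (end > n - 1) {
        warning("promoter truncated at contig edge for gene ", gene_table$gene_id[i])
        end <- n - 1
      }
      out[i] <- reverse_complement(substr(s, tss + 2, end + 1))  # (tss, end]
    }
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
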