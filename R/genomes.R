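#' Read haplotype genomes from FASTA
#'
#' Reads one or more FASTA files into a genome set: one row per sample, in
#' file/record order (the order that defines color bits). Multi-record
#' files contribute one sample per record.
#'
#' @param paths character vector of FASTA file paths.
#' @return a tibble with columns `sample_id`, `sequence`.
#' @export
read_genomes <- function(paths) {
  recs <- lapply(paths, Biostrings::readDNAStringSet)
  x <- do.call(c, recs)
  tibble::tibble(
    sample_id = sub("\\s.*$", "", names(x)),
    sequence  = unname(toupper(as.character(x)))
  )
}

#' Write a genome set to FASTA
#'
#' @param genomes tibble with `sample_id`, `sequence`.
#' @param path output file.
#' @export
write_genomes <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes$sequence)
  names(x) <- genomes$sample_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
           "B", "D", "H", "V", "N")

#' Replace degenerate bases by the column majority of the other samples
#'
#' Ambiguous IUPAC codes are intractable for k-mer graphs, so each
#' degenerate base is replaced by the most frequent base at the same
#' position among the *other* sequences (ties broken by the
#' lexicographically smallest base, for determinism), and the edit is
#' logged. Positions are 1-based.
#'
#' @param genomes tibble with `sample_id`, `sequence` (IUPAC alphabet).
#' @return the genome set with sequences over {A,C,G,T} and a
#'   `modifications` list-column of tibbles (`position`, `original`,
#'   `replacement`).
#' @export
sanitize_genomes <- function(genomes) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 2)
  if (any(!nzchar(genomes$sequence))) stop("empty sequence in input")
  seqs <- toupper(genomes$sequence)
  bad <- stringr::str_detect(seqs, paste0("[^", paste(IUPAC, collapse = ""), "]"))
  if (any(bad)) {
    stop("non-IUPAC characters in sample(s): ",
         paste(genomes$sample_id[bad], collapse = ", "))
  }
  need <- stringr::str_detect(seqs, "[^ACGT]")
  mods <- rep(list(tibble::tibble(position = integer(), original = character(),
                                  replacement = character())), length(seqs))
  if (any(need)) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    for (i in which(need)) {
      pos <- which(!chars[[i]] %in% c("A", "C", "G", "T"))
      for (p in pos) {
        others <- vapply(chars[-i], function(ch) {
          if (p <= length(ch)) ch[p] else NA_character_
        }, character(1))
        others <- others[!is.na(others) & others %in% c("A", "C", "G", "T")]
        if (length(others) == 0) {
          stop("position ", p, ": no other sample offers an unambiguous base",
               call. = FALSE)
        }
        tab <- table(others)
        best <- sort(names(tab)[tab == max(tab)])[1]
        mods[[i]] <- dplyr::bind_rows(
          mods[[i]],
          tibble::tibble(position = p, original = chars[[i]][p],
                         replacement = best))
        chars[[i]][p] <- best
      }
      seqs[i] <- paste(chars[[i]], collapse = "")
    }
  }
  out <- genomes
  out$sequence <- seqs
  out$modifications <- mods
  out
}

#' Length of the longest repeated substring
#'
#' Longest substring occurring at least twice (occurrences may overlap);
#' 0 when every character is distinct or the sequence is empty. Used to
#' pick a k that keeps each sample's k-mers unique.
#'
#' @param sequence a single string over {A,C,G,T}.
#' @return integer repeat length.
#' @export
longest_repeat_length <- function(sequence) {
  n <- nchar(sequence)
  if (n < 2) return(0L)
  has_rep <- function(L) {
    if (L > n - 1) return(FALSE)
    anyDuplicated(substring(sequence, 1:(n - L + 1), L:n)) > 0
  }
  if (!has_rep(1L)) return(0L)
  # exponential then binary search on the largest L with a repeat
  lo <- 1L
  hi <- 2L
  while (hi <= n - 1 && has_rep(hi)) {
    lo <- hi
    hi <- hi * 2L
  }
  hi <- min(hi, n - 1L)
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1) %/% 2)
    if (has_rep(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Choose the k-mer length
#'
#' With K the maximum longest-repeat length over the samples, any k > K
#' keeps every sample's path free of repeated k-mers and the graph is
#' (almost surely) acyclic. Defaults to K + 1; an explicit `k` at or below
#' K is allowed but triggers a warning that cycle handling may be needed.
#'
#' @param genomes sanitized genome set.
#' @param k optional requested value (>= 2).
#' @return integer k.
#' @export
choose_k <- function(genomes, k = NULL) {
  K <- max(vapply(genomes$sequence, longest_repeat_length, integer(1),
                  USE.NAMES = FALSE))
  if (is.null(k)) {
    return(max(K + 1L, 2L))
  }
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  if (k <= K) {
    warning("k = ", k, " is not above the longest repeat length K = ", K,
            "; the graph may contain cycles (see detect_cycles())",
            call. = FALSE)
  }
  k
}

#' Generate anchor segments
#'
#' Draws two random length-k segments over ACGT to prepend (head) and
#' append (tail) to every sample, guaranteeing a single start and end node.
#' Neither segment may occur as a substring of any input sequence (they
#' only anchor; they must not touch the graph's interior), and head != tail.
#' Deterministic for a fixed seed.
#'
#' @param k segment length (>= 2).
#' @param genomes genome set whose sequences the anchors must avoid.
#' @param seed integer seed.
#' @param max_tries bounded retry count before giving up.
#' @return named character vector `c(head = , tail = )`.
#' @export
generate_anchors <- function(k, genomes, seed = 1L, max_tries = 1000L) {
  stopifnot(k >= 2)
  seqs <- genomes$sequence
  withr::with_seed(seed, {
    draw <- function() paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                             collapse = "")
    ok <- function(s) !any(stringr::str_detect(seqs, stringr::fixed(s)))
    head <- NULL
    for (i in seq_len(max_tries)) {
      cand <- draw()
      if (ok(cand)) { head <- cand; break }
    }
    if (is.null(head)) stop("no admissible head anchor after ", max_tries,
                            " draws", call. = FALSE)
    tail <- NULL
    for (i in seq_len(max_tries)) {
      cand <- draw()
      if (cand != head && ok(cand)) { tail <- cand; break }
    }
    if (is.null(tail)) stop("no admissible tail anchor after ", max_tries,
                            " draws", call. = FALSE)
    c(head = head, tail = tail)
  })
}
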