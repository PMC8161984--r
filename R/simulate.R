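#' Simulate a mitogenome-like haplotype population
#'
#' Generates (or takes) a reference sequence and derives the remaining
#' samples by placing a configured number of substitutions, deletions and
#' insertions per sample at uniform random, non-overlapping positions
#' (events of one sample never overlap each other; samples are mutated
#' independently). Indel lengths are uniform on `indel_len`, capped below
#' 50 bp; substitution alleles are uniform over the three alternatives.
#' Defaults emulate a human-mitogenome-scale experiment: a 16.5 kb
#' reference and 10 samples (reference included). Deterministic per seed.
#'
#' @param n_samples total samples including the reference (default 10).
#' @param ref_length reference length when `reference` is NULL.
#' @param reference optional reference sequence string.
#' @param snp,del,ins per-sample event counts.
#' @param indel_len inclusive indel length range (1..49).
#' @param seed integer seed.
#' @return list with `genomes` (tibble `sample_id`, `sequence`; the
#'   reference is sample `"ref"`, first) and `truth` (tibble `sample_id`,
#'   `refpos`, `ref`, `alt`, `vartype` in VCF-style left-anchored form).
#' @export
simulate_population <- function(n_samples = 10L, ref_length = 16500L,
                                reference = NULL, snp = 100L, del = 0L,
                                ins = 0L, indel_len = c(1L, 49L),
                                seed = 1L) {
  stopifnot(n_samples >= 2, snp >= 0, del >= 0, ins >= 0)
  if (indel_len[2] >= 50L) stop("indel lengths must stay below 50 bp")
  withr::with_seed(seed, {
    if (is.null(reference)) {
      reference <- paste(sample(c("A", "C", "G", "T"), ref_length,
                                replace = TRUE), collapse = "")
    }
    L <- nchar(reference)
    refv <- strsplit(reference, "", fixed = TRUE)[[1]]
    n_events <- snp + del + ins
    samples <- paste0("sample", seq_len(n_samples - 1L))
    truth <- list()
    seqs <- character(n_samples - 1L)
    for (si in seq_along(samples)) {
      # draw non-overlapping event windows (position 1 and L are kept
      # intact so indels always have a left anchor inside the sequence)
      len_range <- seq(indel_len[1], indel_len[2])
      lens <- c(rep(1L, snp),
                if (del + ins > 0)
                  len_range[sample.int(length(len_range), del + ins,
                                       replace = TRUE)] else integer(0))
      types <- c(rep(1L, snp), rep(2L, del), rep(3L, ins))
      ord <- sample(seq_along(types))
      lens <- lens[ord]; types <- types[ord]
      pos <- integer(0)
      used <- logical(L)
      used[1] <- used[L] <- TRUE
      for (e in seq_along(types)) {
        w <- if (types[e] == 2L) lens[e] + 1L else 1L   # window on reference
        ok <- FALSE
        for (try in 1:200) {
          p <- sample(2:(L - w), 1L)
          if (!any(used[(p - 1L):(p + w)])) { ok <- TRUE; break }
        }
        if (!ok) stop("requested variants exceed the available positions")
        used[(p - 1L):(p + w)] <- TRUE
        pos[e] <- p
      }
      events <- tibble::tibble(pos = pos, type = types, len = lens) |>
        dplyr::arrange(pos)
      out <- character(0)
      cur <- 1L
      for (e in seq_len(nrow(events))) {
        p <- events$pos[e]; ty <- events$type[e]; ln <- events$len[e]
        out <- c(out, refv[cur:(p - 1L)])
        if (ty == 1L) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), refv[p]), 1L)
          out <- c(out, alt)
          cur <- p + 1L
          truth[[length(truth) + 1L]] <- tibble::tibble(
            sample_id = samples[si], refpos = p, ref = refv[p], alt = alt,
            vartype = 1L)
        } else if (ty == 2L) {
          # delete ref[p+1 .. p+ln], left-anchored at p; normalize the
          # record leftwards so it matches left-aligned VCF calls
          out <- c(out, refv[p])
          cur <- p + ln + 1L
          q <- p
          while (q > 1L && refv[q + ln] == refv[q]) q <- q - 1L
          truth[[length(truth) + 1L]] <- tibble::tibble(
            sample_id = samples[si], refpos = q,
            ref = paste(refv[q:(q + ln)], collapse = ""), alt = refv[q],
            vartype = 2L)
        } else {
          insv <- sample(c("A", "C", "G", "T"), ln, replace = TRUE)
          out <- c(out, refv[p], insv)
          cur <- p + 1L
          q <- p; iv <- insv
          while (q > 1L && iv[length(iv)] == refv[q]) {
            iv <- c(refv[q], iv[-length(iv)])
            q <- q - 1L
          }
          truth[[length(truth) + 1L]] <- tibble::tibble(
            sample_id = samples[si], refpos = q, ref = refv[q],
            alt = paste(c(refv[q], iv), collapse = ""), vartype = 3L)
        }
      }
      out <- c(out, refv[cur:L])
      seqs[si] <- paste(out, collapse = "")
    }
    genomes <- tibble::tibble(sample_id = c("ref", samples),
                              sequence = c(reference, seqs))
    truth <- if (length(truth)) dplyr::bind_rows(truth) else {
      tibble::tibble(sample_id = character(), refpos = integer(),
                     ref = character(), alt = character(),
                     vartype = integer())
    }
    list(genomes = genomes, truth = dplyr::arrange(truth, refpos, sample_id))
  })
}

#' Precision and recall of calls against a simulation truth set
#'
#' Location mode matches a call to the truth when their reference
#' positions agree within the tolerance (default 0 for substitutions and
#' 1 for indels, absorbing left-anchoring ambiguity); type mode
#' additionally requires the variant type to agree (unsure calls, type 4,
#' match either indel type). Truth records are collapsed to unique loci
#' (position in location mode, position + type in type mode). Precision is
#' `tp / (tp + fp)` (1 when no calls), recall `tp / (tp + fn)`.
#'
#' @param calls a `variant_calls` tibble (or any tibble with `refpos`,
#'   `vartype`).
#' @param truth simulation truth tibble (`refpos`, `vartype`).
#' @param mode `"location"` or `"type"`.
#' @param tolerance named or unnamed tolerance: a single integer applied
#'   to indels (substitutions stay exact), default 1.
#' @return one-row tibble of class `variant_eval`: `mode`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`.
#' @export
evaluate_calls <- function(calls, truth, mode = c("location", "type"),
                           tolerance = 1L) {
  mode <- match.arg(mode)
  tru <- if (mode == "location") {
    dplyr::distinct(tibble::tibble(refpos = truth$refpos,
                                   vartype = truth$vartype), refpos,
                    .keep_all = TRUE)
  } else {
    dplyr::distinct(tibble::tibble(refpos = truth$refpos,
                                   vartype = truth$vartype))
  }
  tol_of <- function(vt) ifelse(vt == 1L, 0L, as.integer(tolerance))
  matched_truth <- logical(nrow(tru))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(calls))) {
    vt <- calls$vartype[i]
    tol <- tol_of(vt)
    hit <- which(abs(tru$refpos - calls$refpos[i]) <= tol)
    if (mode == "type" && length(hit)) {
      hit <- hit[tru$vartype[hit] == vt |
                   (vt == 4L & tru$vartype[hit] %in% c(2L, 3L))]
    }
    if (length(hit)) {
      tp <- tp + 1L
      matched_truth[hit] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  fn <- sum(!matched_truth)
  out <- tibble::tibble(
    mode = mode, tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn))
  class(out) <- c("variant_eval", class(out))
  out
}
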