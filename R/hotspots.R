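# Hotspot peptide windows: contiguous sequence stretches of one interface
# partner ranked by how many atomic contacts they make with the other
# partner, a direct route to short (<= 16 residue) candidate binder
# peptides mimicking one side of the interface.

#' Rank contiguous sequence windows by interface-contact density
#'
#' Every contiguous window of `minLen` to `maxLen` residues of `chainId`
#' (the residues of the analyzed selection, in sequence order) is scored by
#' its total number of atomic contacts with the partner selection
#' (`nContacts`) and its summed 0-9 burial codes (`nBuried`). Windows are
#' ordered by `nContacts` descending, ties by `nBuried` descending, then by
#' N-terminal position (and shorter window first as the final tie-break).
#'
#' @param summaries data.frame from [summarizePairs()].
#' @param burials data.frame from [residueBurial()] (defines the residue set
#'   and order of the window chain).
#' @param chainId chain of the selection to design windows on.
#' @param minLen,maxLen inclusive window-length bounds (defaults 4 and 16).
#' @return data.frame of windows: `chain`, `startRes`, `endRes`, `length`,
#'   `nContacts`, `nBuried`.
#' @export
rankWindows <- function(summaries, burials, chainId, minLen = 4L,
                        maxLen = 16L) {
  stopifnot(minLen >= 1, maxLen >= minLen)
  res <- burials[burials$chain == chainId, , drop = FALSE]
  res <- res[!duplicated(paste(res$resno, res$icode)), , drop = FALSE]
  res <- res[order(res$resno, res$icode), , drop = FALSE]
  empty <- data.frame(chain = character(), startRes = integer(),
                      endRes = integer(), length = integer(),
                      nContacts = integer(), nBuried = integer(),
                      stringsAsFactors = FALSE)
  n <- nrow(res)
  if (n < minLen) return(empty)
  # per-residue atomic contact counts against the partner
  total <- summaries$nPolar + summaries$nNonpolar + summaries$nOther +
    summaries$nUntyped
  perRes <- numeric(n)
  key <- paste(res$resno, res$icode)
  k1 <- paste(summaries$resno1, summaries$icode1)
  k2 <- paste(summaries$resno2, summaries$icode2)
  for (i in seq_len(n)) {
    perRes[i] <- sum(total[summaries$chain1 == chainId & k1 == key[i]]) +
      sum(total[summaries$chain2 == chainId & k2 == key[i]])
  }
  cumC <- cumsum(c(0, perRes))
  cumB <- cumsum(c(0, res$bin))
  out <- list()
  for (len in seq(minLen, min(maxLen, n))) {
    starts <- seq_len(n - len + 1)
    out[[length(out) + 1]] <- data.frame(
      chain = chainId, startRes = res$resno[starts],
      endRes = res$resno[starts + len - 1], length = len,
      nContacts = cumC[starts + len] - cumC[starts],
      nBuried = cumB[starts + len] - cumB[starts],
      startPos = starts, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$nContacts, -out$nBuried, out$startPos, out$length), ,
             drop = FALSE]
  out$startPos <- NULL
  rownames(out) <- NULL
  out
}

#' Greedily select non-overlapping top windows
#'
#' Scans the ranked window list and keeps a window only if it shares no
#' residue with an already-kept window, stopping after `k` windows — so the
#' reported candidate peptides are disjoint stretches of sequence.
#'
#' @param windows ranked data.frame from [rankWindows()].
#' @param k maximum number of windows to keep.
#' @return The kept subset, in rank order.
#' @export
selectNonoverlapping <- function(windows, k) {
  keep <- integer(0)
  for (i in seq_len(nrow(windows))) {
    if (length(keep) >= k) break
    ok <- TRUE
    for (j in keep) {
      if (windows$chain[i] == windows$chain[j] &&
          windows$startRes[i] <= windows$endRes[j] &&
          windows$startRes[j] <= windows$endRes[i]) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
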