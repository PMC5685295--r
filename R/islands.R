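#' Find CpG islands in a DNA sequence
#'
#' Sliding-window CpG island detection in the Gardiner-Garden tradition: a
#' window of `min_len` bp (step 1) qualifies when its GC fraction exceeds
#' `min_gc` and its observed-to-expected CpG ratio,
#' `count(CG) * L / (count(C) * count(G))`, exceeds `min_oe`. Overlapping
#' or adjacent qualifying windows are merged; each merged interval is then
#' re-tested and trimmed symmetrically from both ends until the whole
#' interval satisfies both criteria, or discarded if it shrinks below
#' `min_len`. Windows containing `N` never qualify.
#'
#' @param seq A single DNA string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive), or a `Biostrings::DNAString`.
#' @param min_len Minimum island length in bp (default 500).
#' @param min_gc GC fraction that must be exceeded (default 0.55).
#' @param min_oe Observed/expected CpG ratio that must be exceeded
#'   (default 0.65).
#' @return A tibble with columns `start`, `end` (1-based inclusive),
#'   `length`, `gc`, `obs_exp`; zero rows when nothing qualifies or the
#'   sequence is shorter than `min_len`.
#' @examples
#' find_cpg_islands(strrep("CG", 300))
#' @export
find_cpg_islands <- function(seq, min_len = 500, min_gc = 0.55,
                             min_oe = 0.65) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1)
  n <- nchar(seq)
  empty <- tibble(start = integer(0), end = integer(0), length = integer(0),
                  gc = double(0), obs_exp = double(0))
  if (n < min_len) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence contains characters outside {A, C, G, T, N}")
  }
  # cumulative counts allow O(1) window statistics
  cum <- list(
    C = cumsum(chars == "C"),
    G = cumsum(chars == "G"),
    N = cumsum(chars == "N"),
    CG = cumsum(c(chars[-n] == "C" & chars[-1] == "G", FALSE))
  )
  win_count <- function(cm, from, to) {
    # pmax keeps the subscript in range; a 0 index would silently drop
    # an element and shift every later window
    cm[to] - ifelse(from > 1, cm[pmax(from - 1, 1)], 0)
  }

  starts <- seq_len(n - min_len + 1)
  ends <- starts + min_len - 1
  cC <- win_count(cum$C, starts, ends)
  cG <- win_count(cum$G, starts, ends)
  cN <- win_count(cum$N, starts, ends)
  # CG dinucleotides starting within the window
  cCG <- win_count(cum$CG, starts, pmax(ends - 1, starts))
  gc <- (cC + cG) / min_len
  oe <- ifelse(cC > 0 & cG > 0, cCG * min_len / (cC * cG), 0)
  ok <- cN == 0 & gc > min_gc & oe > min_oe
  if (!any(ok)) return(empty)

  # merge overlapping/adjacent qualifying windows
  qs <- starts[ok]
  qe <- ends[ok]
  merged_s <- integer(0)
  merged_e <- integer(0)
  cur_s <- qs[1]
  cur_e <- qe[1]
  if (length(qs) > 1) {
    for (i in 2:length(qs)) {
      if (qs[i] <= cur_e + 1) {
        cur_e <- max(cur_e, qe[i])
      } else {
        merged_s <- c(merged_s, cur_s)
        merged_e <- c(merged_e, cur_e)
        cur_s <- qs[i]
        cur_e <- qe[i]
      }
    }
  }
  merged_s <- c(merged_s, cur_s)
  merged_e <- c(merged_e, cur_e)

  stats_of <- function(s, e) {
    L <- e - s + 1
    cC <- win_count(cum$C, s, e)
    cG <- win_count(cum$G, s, e)
    cCG <- if (e > s) win_count(cum$CG, s, e - 1) else 0
    gc <- (cC + cG) / L
    oe <- if (cC > 0 && cG > 0) cCG * L / (cC * cG) else 0
    c(gc = gc, oe = oe)
  }
  qualifies <- function(s, e) {
    if (win_count(cum$N, s, e) > 0) return(FALSE)
    st <- stats_of(s, e)
    st["gc"] > min_gc && st["oe"] > min_oe
  }

  out <- list()
  for (i in seq_along(merged_s)) {
    s <- merged_s[i]
    e <- merged_e[i]
    # re-test the merged interval and shrink one base from each end per
    # round until it passes whole or becomes too short
    while (e - s + 1 >= min_len && !qualifies(s, e)) {
      s <- s + 1
      e <- e - 1
    }
    if (e - s + 1 >= min_len) {
      st <- stats_of(s, e)
      out[[length(out) + 1]] <- tibble(
        start = s, end = e, length = e - s + 1,
        gc = unname(st["gc"]), obs_exp = unname(st["oe"])
      )
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}
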