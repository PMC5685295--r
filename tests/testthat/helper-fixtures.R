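# in-code fixtures shared across test files

# a small hand-written manifest: two genes, TSS + body islands, shores,
# one multi-gene probe, one multi-site probe
make_manifest <- function() {
  tibble::tibble(
    probe_id = sprintf("cg%02d", 1:10),
    gene_symbol = c("A", "A", "A", "A", "A", "B", "B", "B", "A;B", "B"),
    chrom = c(rep("chr1", 8), "chr1", "chr-MULTI"),
    pos = c(1000L, 1040L, 1080L, 5000L, 9000L, 20000L, 20040L, 24000L,
            26000L, 28000L),
    gene_region = c("TSS1500", "TSS200", "FirstExon", "Body", "Intergenic",
                    "TSS200", "UTR5", "Body", "Body", "Body"),
    island_relation = c("Island", "Island", "Island", "Island", "OpenSea",
                        "Island", "Island", "Island", "S_Shore", "OpenSea"),
    island_id = c("CGI_A_TSS", "CGI_A_TSS", "CGI_A_TSS", "CGI_A_BODY", NA,
                  "CGI_B_TSS", "CGI_B_TSS", "CGI_B_BODY", NA, NA),
    gene_symbols = lapply(
      c("A", "A", "A", "A", "A", "B", "B", "B", "A;B", "B"),
      function(x) strsplit(x, ";")[[1]]),
    multi_gene = c(rep(FALSE, 8), TRUE, FALSE)
  )
}

make_beta <- function(values) {
  # values: named list sample -> numeric vector over the 10 probes
  tibble::as_tibble(c(list(probe_id = sprintf("cg%02d", 1:10)), values))
}

make_detp <- function(samples, p = 0.001) {
  vals <- stats::setNames(rep(list(rep(p, 10)), length(samples)), samples)
  tibble::as_tibble(c(list(probe_id = sprintf("cg%02d", 1:10)), vals))
}

# brute-force window scan used as the independent oracle for island finding
brute_force_islands <- function(seq, min_len = 500, min_gc = 0.55,
                                min_oe = 0.65) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < min_len) return(cbind(start = integer(0), end = integer(0)))
  ok <- logical(n - min_len + 1)
  for (s in seq_len(n - min_len + 1)) {
    w <- chars[s:(s + min_len - 1)]
    if (any(w == "N")) next
    cC <- sum(w == "C"); cG <- sum(w == "G")
    cg <- sum(w[-min_len] == "C" & w[-1] == "G")
    gc <- (cC + cG) / min_len
    oe <- if (cC > 0 && cG > 0) cg * min_len / (cC * cG) else 0
    ok[s] <- gc > min_gc && oe > min_oe
  }
  if (!any(ok)) return(cbind(start = integer(0), end = integer(0)))
  starts <- which(ok)
  ends <- starts + min_len - 1
  ms <- starts[1]; me <- ends[1]
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1) me <- max(me, ends[i])
    else { out <- rbind(out, c(ms, me)); ms <- starts[i]; me <- ends[i] }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}
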