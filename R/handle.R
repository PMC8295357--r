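#' Tracking-handle sequence geometry
#'
#' The tracking handle is a single-stranded DNA of repeated imager-binding
#' registers; the default 54-nt handle is a poly-(TCC) repeat complementary to
#' the 8-nt imager 5'-GAGGAGGA-3'. Because the registers overlap, the number
#' of imagers that can bind simultaneously is limited by footprint exclusion,
#' not by the number of sequence matches.
#'
#' @param length_nt handle length in nucleotides (default 54).
#' @return A character scalar, the handle sequence 5'->3'.
#' @examples
#' th_handle_sequence()          # 54-nt poly-(TCC) repeat
#' @export
th_handle_sequence <- function(length_nt = 54L) {
  stopifnot(length_nt >= 1L)
  substr(strrep("TCC", ceiling(length_nt / 3)), 1L, length_nt)
}

#' Maximum number of simultaneously bound imagers on a handle
#'
#' Enumerates all binding windows of the imager on the handle (positions where
#' the reverse complement of the imager sequence occurs) and computes the
#' maximum set of mutually non-overlapping windows. Each bound imager occupies
#' its full footprint, so two imagers cannot share a nucleotide. The maximum
#' independent set of intervals is found by the exchange-optimal greedy rule
#' (earliest end first), which is exact for interval scheduling.
#'
#' @param handle handle sequence 5'->3' (character or
#'   [Biostrings::DNAString]); default the 54-nt repeat handle.
#' @param imager imager sequence 5'->3' (default `"GAGGAGGA"`, 8 nt).
#' @return Integer: the maximum number of simultaneously bound imagers. The
#'   selected footprint start positions are attached as attribute
#'   `"footprints"`.
#' @examples
#' max_bound_imagers()   # 6 on the default 54-nt handle
#' @export
max_bound_imagers <- function(handle = th_handle_sequence(),
                              imager = "GAGGAGGA") {
  handle <- Biostrings::DNAString(as.character(handle))
  site <- Biostrings::reverseComplement(Biostrings::DNAString(as.character(imager)))
  m <- Biostrings::matchPattern(site, handle)
  if (length(m) == 0L) {
    out <- 0L
    attr(out, "footprints") <- integer(0)
    return(out)
  }
  s <- Biostrings::start(m); e <- Biostrings::end(m)
  o <- order(e)
  s <- s[o]; e <- e[o]
  chosen <- integer(0)
  last_end <- 0L
  for (i in seq_along(s)) {
    if (s[i] > last_end) {
      chosen <- c(chosen, s[i])
      last_end <- e[i]
    }
  }
  out <- length(chosen)
  attr(out, "footprints") <- chosen
  out
}
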