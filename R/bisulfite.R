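#' @title Absolute methylation rates from bisulfite Sanger traces
#'
#' @description
#' After bisulfite conversion and PCR, an unmethylated cytosine reads as T
#' while a methylated cytosine stays C. At each GC-dinucleotide cytosine
#' of the (unconverted) reference, the methylation rate is therefore the C
#' fraction of the trace intensities, `I_C / (I_C + I_T)`. The module
#' consumes a per-position four-channel intensity table exported from
#' trace software; chromatogram parsing is out of scope.
#'
#' @name bisulfite
NULL

#' GC-site positions of a reference sequence
#'
#' Positions (1-based) of the C in every "GC" dinucleotide on the forward
#' strand; with `strand = "reverse"`, positions of the G (the base paired
#' with the reverse-strand C of the same dinucleotide, which GC's own
#' reverse complement places on the forward G).
#'
#' @param reference character scalar, unconverted reference sequence.
#' @param strand `"forward"` (default) or `"reverse"`.
#' @return integer vector of positions.
#' @export
gc_sites <- function(reference, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  bases <- strsplit(toupper(reference), "")[[1L]]
  if (length(bases) < 2L) return(integer(0))
  g <- which(bases[-length(bases)] == "G" & bases[-1L] == "C")
  if (strand == "forward") g + 1L else g
}

#' Read a trace-intensity TSV
#'
#' Expected columns: `position`, `ref_base`, `I_A`, `I_C`, `I_G`, `I_T`.
#'
#' @param path file path.
#' @return trace profile data.frame.
#' @export
read_trace <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE)
  need <- c("position", "ref_base", "I_A", "I_C", "I_G", "I_T")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("trace TSV lacks column(s): ",
    paste(miss, collapse = ", "))
  tab
}

#' Per-GC-site methylation rates from a trace profile
#'
#' @param trace trace profile data.frame (`position`, `ref_base`, `I_A`,
#'   `I_C`, `I_G`, `I_T`), positions 1..n in order.
#' @param reference optional reference sequence; defaults to
#'   `trace$ref_base` concatenated.
#' @param strand which strand's GC cytosines to score, see [gc_sites()].
#' @return list of class `"methylation_profile"`: `sites` (data.frame
#'   `position`, `rate`) and `mean_rate`.
#' @export
methylation_rates <- function(trace, reference = NULL,
                              strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  if (is.null(reference)) {
    reference <- paste(trace$ref_base, collapse = "")
  }
  if (nchar(reference) != nrow(trace)) {
    stop("reference length must equal trace length")
  }
  inten <- as.matrix(trace[, c("I_A", "I_C", "I_G", "I_T")])
  if (any(inten < 0)) stop("intensities must be >= 0")
  if (any(rowSums(inten) <= 0)) {
    stop("every position needs at least one positive channel")
  }
  sites <- gc_sites(reference, strand)
  if (length(sites) == 0L) stop("reference contains no GC dinucleotide")
  if (strand == "forward") {
    num <- trace$I_C[sites]
    den <- trace$I_C[sites] + trace$I_T[sites]
  } else {
    # reverse-strand C pairs with the forward G; conversion reads G -> A
    num <- trace$I_G[sites]
    den <- trace$I_G[sites] + trace$I_A[sites]
  }
  usable <- den > 0
  if (!all(usable)) {
    warning(sum(!usable), " GC site(s) with zero C+T intensity skipped")
  }
  out <- data.frame(position = sites[usable],
    rate = num[usable] / den[usable])
  structure(list(sites = out, mean_rate = mean(out$rate)),
    class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat("methylation_profile: ", nrow(x$sites), " GC sites, mean rate ",
    signif(x$mean_rate, 4), "\n", sep = "")
  invisible(x)
}
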