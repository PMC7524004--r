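# Node populations and network layout for the two-subnetwork C-T-C circuit.

POPULATIONS <- c("PY", "IN", "TC", "RE", "NT")
REGIONS <- c("focal", "surrounding", "external")

# Sign of every outgoing coupling is fixed by the source population:
# pyramidal (PY), thalamocortical relay (TC) and trigeminal (NT) nodes are
# excitatory; cortical interneurons (IN) and reticular thalamic (RE) nodes
# are inhibitory.
POPULATION_SIGN <- c(PY = 1, IN = -1, TC = 1, RE = -1, NT = 1)

DEFAULT_COUNTS <- c(
  PY.focal = 40L, IN.focal = 10L, TC.focal = 40L, RE.focal = 40L,
  PY.surrounding = 160L, IN.surrounding = 40L, TC.surrounding = 80L,
  RE.surrounding = 80L, NT.external = 10L
)

#' Network layout: compartment sizes and node index ranges
#'
#' Describes how nodes are partitioned into populations (PY, IN, TC, RE, NT)
#' and regions (focal, surrounding, external). Node indices are contiguous,
#' 1-based, and ordered trigeminal first, then focal thalamus and cortex,
#' then the surrounding thalamus and cortex, mirroring the block structure of
#' the composed coupling matrix.
#'
#' Default compartment sizes are 40 focal PY, 10 focal IN, 40 focal TC,
#' 40 focal RE, 160 surrounding PY, 40 surrounding IN, 80 surrounding TC,
#' 80 surrounding RE and 10 NT nodes: 500 nodes in total.
#'
#' @param region one of `"full"` (default), `"focal"` (focal compartments
#'   plus the external trigeminal input) or `"surrounding"`.
#' @param counts optional named integer vector overriding compartment sizes;
#'   names are `"<population>.<region>"`, e.g. `"PY.focal"`.
#' @return an object of class `swd_layout`: a data frame with one row per
#'   compartment (`population`, `region`, `n`, `first`, `last`) and
#'   attribute `n_total`.
#' @export
#' @examples
#' layout <- network_layout()
#' attr(layout, "n_total")  # 500
network_layout <- function(region = c("full", "focal", "surrounding"),
                           counts = NULL) {
  region <- match.arg(region)
  cts <- DEFAULT_COUNTS
  if (!is.null(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(cts)))
      stop("counts must be named '<population>.<region>', e.g. 'PY.focal'")
    if (any(counts < 0) || any(counts != round(counts)))
      stop("compartment counts must be nonnegative integers")
    cts[names(counts)] <- as.integer(counts)
  }
  keep <- switch(region,
    full = names(cts),
    # focal candidate matrices keep the trigeminal input compartment, since
    # NT projects only onto focal TC nodes
    focal = c("NT.external", "PY.focal", "IN.focal", "TC.focal", "RE.focal"),
    surrounding = c("PY.surrounding", "IN.surrounding", "TC.surrounding",
                    "RE.surrounding")
  )
  # block order: NT, focal thalamus + cortex, surrounding thalamus + cortex
  order_full <- c("NT.external",
                  "TC.focal", "RE.focal", "PY.focal", "IN.focal",
                  "TC.surrounding", "RE.surrounding", "PY.surrounding",
                  "IN.surrounding")
  keep <- order_full[order_full %in% keep]
  parts <- strsplit(keep, ".", fixed = TRUE)
  df <- data.frame(
    population = vapply(parts, `[`, "", 1L),
    region = vapply(parts, `[`, "", 2L),
    n = unname(cts[keep]),
    stringsAsFactors = FALSE
  )
  df <- df[df$n > 0L, , drop = FALSE]
  ends <- cumsum(df$n)
  df$first <- c(1L, head(ends, -1L) + 1L)
  df$last <- ends
  rownames(df) <- NULL
  structure(df, n_total = sum(df$n), class = c("swd_layout", "data.frame"))
}

#' Node indices of a compartment
#'
#' @param layout an `swd_layout`.
#' @param population optional population filter (any of PY, IN, TC, RE, NT).
#' @param region optional region filter (focal, surrounding, external).
#' @return 1-based node indices, in layout order.
#' @export
layout_indices <- function(layout, population = NULL, region = NULL) {
  stopifnot(inherits(layout, "swd_layout"))
  sel <- rep(TRUE, nrow(layout))
  if (!is.null(population)) sel <- sel & layout$population %in% population
  if (!is.null(region)) sel <- sel & layout$region %in% region
  rows <- which(sel)
  if (length(rows) == 0L) return(integer(0))
  unlist(lapply(rows, function(r) seq.int(layout$first[r], layout$last[r])),
         use.names = FALSE)
}

#' @export
print.swd_layout <- function(x, ...) {
  cat("<swd_layout> ", attr(x, "n_total"), " nodes\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# population label of every node, as a character vector of length n_total
node_populations <- function(layout) {
  rep(layout$population, layout$n)
}

node_regions <- function(layout) {
  rep(layout$region, layout$n)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
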