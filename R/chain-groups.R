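#' @include AllClasses.R
NULL

## one-letter sequence of a chain (unknown residues -> X)
.chain_seq <- function(s, chain) {
  r <- s@residues[s@residues$chain == chain, , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(r$resid))
  aa[is.na(aa) | aa == ""] <- "X"
  paste(aa, collapse = "")
}

## global alignment of two one-letter sequences; returns list(pid, map)
## where map is a 2-column matrix of matched residue positions
.align_chains <- function(seq1, seq2) {
  aln <- Biostrings::pairwiseAlignment(seq1, seq2, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  g1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  g2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i1 <- 0L; i2 <- 0L
  map <- matrix(0L, nrow = 0, ncol = 2)
  pairs <- vector("list", length(g1))
  np <- 0L
  for (p in seq_along(g1)) {
    a <- g1[p] != "-"; b <- g2[p] != "-"
    if (a) i1 <- i1 + 1L
    if (b) i2 <- i2 + 1L
    if (a && b) { np <- np + 1L; pairs[[np]] <- c(i1, i2) }
  }
  if (np) map <- do.call(rbind, pairs[seq_len(np)])
  list(pid = Biostrings::pid(aln), map = map)
}

#' Group homologous chains of an assembly
#'
#' Chains are grouped by pairwise global sequence identity (threshold 95%
#' by default), the operational proxy for "homologous monomers" of an
#' oligomer. Within each group, residues are put into correspondence by the
#' global alignment against the group's first chain; only aligned positions
#' present in every chain of the group are kept, so each group yields a
#' monomer-length view usable for profile averaging.
#'
#' @param s a [CalphaStructure].
#' @param identityThreshold percent identity for same-group membership.
#' @return a [ChainGroups] object.
#' @export
groupHomologousChains <- function(s, identityThreshold = 95) {
  stopifnot(is(s, "CalphaStructure"))
  chains <- unique(s@residues$chain)
  n <- length(chains)
  seqs <- vapply(chains, function(ch) .chain_seq(s, ch), character(1))

  ## union-find over the identity graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  alns <- list()
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- .align_chains(seqs[i], seqs[j])
      alns[[paste(i, j)]] <- a
      if (a$pid >= identityThreshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(unique(roots), function(r) chains[roots == r])

  keys_of <- function(ch) s@residues$key[s@residues$chain == ch]
  correspondence <- lapply(groups, function(g) {
    idx <- match(g, chains)
    rep_i <- idx[1]
    rep_keys <- keys_of(chains[rep_i])
    ## rep positions aligned in every member
    maps <- lapply(idx, function(j) {
      if (j == rep_i)
        return(cbind(seq_along(rep_keys), seq_along(rep_keys)))
      key <- paste(min(rep_i, j), max(rep_i, j))
      a <- alns[[key]]
      m <- a$map
      if (rep_i > j) m <- m[, 2:1, drop = FALSE]
      m
    })
    common <- Reduce(intersect, lapply(maps, function(m) m[, 1]))
    common <- sort(common)
    mat <- matrix(NA_character_, nrow = length(common), ncol = length(g),
                  dimnames = list(NULL, g))
    for (c_i in seq_along(g)) {
      m <- maps[[c_i]]
      pos <- m[match(common, m[, 1]), 2]
      mat[, c_i] <- keys_of(g[c_i])[pos]
    }
    mat
  })

  new("ChainGroups", groups = groups, correspondence = correspondence,
      identityThreshold = identityThreshold)
}
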