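#' DNA alignments
#'
#' A `jc_alignment` stores a taxa-by-sites integer matrix with states coded
#' 1..4 (A, C, G, T); 0 marks a gap or ambiguous state. Site-pattern
#' compression happens lazily when a likelihood is evaluated.
#'
#' @param states integer matrix with taxon rownames.
#' @export
new_jc_alignment <- function(states) {
  stopifnot(is.matrix(states), !is.null(rownames(states)))
  storage.mode(states) <- "integer"
  structure(list(states = states, taxa = rownames(states)),
            class = "jc_alignment")
}

#' @export
print.jc_alignment <- function(x, ...) {
  cat("<jc_alignment> ", nrow(x$states), " taxa x ", ncol(x$states),
      " sites\n", sep = "")
  invisible(x)
}

#' Number of sites in an alignment
#' @param aln a `jc_alignment`.
#' @export
n_sites <- function(aln) ncol(aln$states)

#' Convert a character matrix or phangorn phyDat to a `jc_alignment`
#'
#' @param x character matrix (values in `a,c,g,t`, case-insensitive; other
#'   symbols become missing) or a `phyDat` object.
#' @export
as_jc_alignment <- function(x) {
  if (inherits(x, "phyDat")) x <- as.character(x)
  stopifnot(is.matrix(x))
  states <- matrix(match(tolower(x), c("a", "c", "g", "t")),
                   nrow(x), ncol(x))
  states[is.na(states)] <- 0L
  rownames(states) <- rownames(x)
  new_jc_alignment(states)
}

#' Concatenate locus alignments
#'
#' Columns are appended in the order given; taxa are aligned by name, and a
#' taxon missing from a locus is padded with gaps.
#'
#' @param alignments list of `jc_alignment`s.
#' @return a `jc_alignment` whose column count is the sum of the inputs',
#'   with integer attribute `locus_boundaries` (cumulative end columns).
#' @export
concatenate_alignments <- function(alignments) {
  if (inherits(alignments, "jc_alignment")) return(alignments)
  stopifnot(length(alignments) >= 1L)
  if (length(alignments) == 1L) return(alignments[[1L]])
  taxa <- Reduce(union, lapply(alignments, function(a) a$taxa))
  mats <- lapply(alignments, function(a) {
    m <- matrix(0L, length(taxa), ncol(a$states))
    m[match(a$taxa, taxa), ] <- a$states
    m
  })
  out <- do.call(cbind, mats)
  rownames(out) <- taxa
  res <- new_jc_alignment(out)
  attr(res, "locus_boundaries") <-
    cumsum(vapply(alignments, n_sites, 0L))
  res
}

#' Write an alignment to FASTA
#'
#' @param aln a `jc_alignment`.
#' @param file output path.
#' @export
write_fasta <- function(aln, file) {
  sym <- c("a", "c", "g", "t")
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$states))) {
    s <- aln$states[i, ]
    chars <- ifelse(s == 0L, "-", sym[pmax(s, 1L)])
    writeLines(c(paste0(">", aln$taxa[i]), paste(chars, collapse = "")),
               con)
  }
  invisible(file)
}

# Compress an alignment into unique site patterns ordered for a given taxon
# ordering. Returns list(tip = ntaxa x npat integer matrix, w = weights).
pattern_data <- function(aln, taxa) {
  idx <- match(taxa, aln$taxa)
  if (anyNA(idx)) stop("alignment lacks taxa: ",
                       paste(setdiff(taxa, aln$taxa), collapse = ", "))
  m <- aln$states[idx, , drop = FALSE]
  nt <- nrow(m)
  if (nt <= 22L) {
    key <- as.vector(5^(seq_len(nt) - 1) %*% m) # exact in double for nt<=22
  } else {
    key <- apply(m, 2L, paste, collapse = ",")
  }
  first <- !duplicated(key)
  pat <- m[, first, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(tip = pat, w = as.numeric(w))
}
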