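#' Pattern families of the ternary symbolic alphabet
#'
#' The 27 length-3 words over \{0,1,2\} partition into eight families of
#' qualitative 3-beat behaviour: the three constant words (`E0`, `E1`, `E2`),
#' low increasing (`LU1`, 8 words), low decreasing (`LD1`, 8 words), fast
#' alternation (`LA1`: 020, 202), peak-like alternation (`P`: 120, 201, 210)
#' and valley-like alternation (`V`: 021, 102, 012).
#'
#' @format Named character vector mapping each word (e.g. `"122"`) to its
#'   family label.
#' @export
hrjsd_families <- function() {
  fam <- c(
    "000" = "E0", "111" = "E1", "222" = "E2",
    "122" = "LU1", "022" = "LU1", "112" = "LU1", "221" = "LU1",
    "220" = "LU1", "211" = "LU1", "121" = "LU1", "212" = "LU1",
    "011" = "LD1", "001" = "LD1", "002" = "LD1", "110" = "LD1",
    "100" = "LD1", "200" = "LD1", "010" = "LD1", "101" = "LD1",
    "020" = "LA1", "202" = "LA1",
    "120" = "P", "201" = "P", "210" = "P",
    "021" = "V", "102" = "V", "012" = "V")
  fam
}

#' Family order used throughout the package
#' @return Character vector of the eight family labels.
#' @export
family_levels <- function() c("E0", "E1", "E2", "LU1", "LD1", "LA1", "P", "V")

#' Symbolize a beat-value sequence
#'
#' Binary coding (`mode = "binary"`): symbol 1 iff the increment to the next
#' beat is strictly positive, else 0. Ternary coding (`mode = "ternary"`,
#' threshold `l` in channel units): 0 for a decrement below `-l`, 1 for an
#' equilibrium change within `[-l, l]`, 2 for an increment above `l`.
#' Conventional thresholds are 5 ms for BBI and 1 mmHg for the pressures.
#'
#' @param x numeric beat-value sequence of length >= 2.
#' @param mode `"binary"` or `"ternary"`.
#' @param threshold equilibrium threshold `l >= 0` (ternary only; ignored and
#'   treated as 0 for binary coding).
#' @return An object of class `symbol_seq`: list with integer `symbols`
#'   (length `length(x) - 1`), `alphabet_size`, and `threshold`.
#' @export
#' @examples
#' symbolize(c(800, 810, 807, 797), mode = "ternary", threshold = 5)$symbols
symbolize <- function(x, mode = c("ternary", "binary"), threshold = 0) {
  mode <- match.arg(mode)
  if (length(x) < 2L)
    stop("at least two values required for symbolization", call. = FALSE)
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  d <- diff(x)
  if (mode == "binary") {
    sym <- as.integer(d > 0)
    k <- 2L
  } else {
    sym <- integer(length(d))
    sym[d < -threshold] <- 0L
    sym[abs(d) <= threshold] <- 1L
    sym[d > threshold] <- 2L
    k <- 3L
  }
  structure(list(symbols = sym, alphabet_size = k, threshold = threshold),
            class = "symbol_seq")
}

word_labels <- function(alphabet_size, k = 3L) {
  grid <- expand.grid(rep(list(0:(alphabet_size - 1L)), k))[, k:1, drop = FALSE]
  apply(grid, 1, paste0, collapse = "")
}

#' Joint word distribution of two symbol sequences
#'
#' Slides a window of length `k` (stride 1) across both sequences
#' simultaneously; each position contributes one (word1, word2) pair. For the
#' ternary alphabet and `k = 3` the result is the 27 x 27 joint word matrix
#' (729 cells); for the binary alphabet it is 8 x 8.
#'
#' @param s1,s2 [symbolize()] outputs of equal length and alphabet.
#' @param k word length, default 3.
#' @return An object of class `joint_word_matrix` with `counts`, `probs`
#'   (both dimension `alphabet^k` square, word-labelled), `word_length`, and
#'   `alphabet_size`.
#' @export
joint_word_distribution <- function(s1, s2, k = 3L) {
  stopifnot(inherits(s1, "symbol_seq"), inherits(s2, "symbol_seq"))
  if (length(s1$symbols) != length(s2$symbols))
    stop("symbol sequences must have equal length", call. = FALSE)
  if (s1$alphabet_size != s2$alphabet_size)
    stop("symbol sequences must share one alphabet", call. = FALSE)
  n <- length(s1$symbols)
  if (n < k) stop("sequences shorter than the word length", call. = FALSE)
  a <- s1$alphabet_size
  labels <- word_labels(a, k)
  nw <- a^k
  # word index = base-a value of the k consecutive symbols
  idx_of <- function(sym) {
    v <- rep(0L, n - k + 1L)
    for (j in seq_len(k)) v <- v * a + sym[j:(n - k + j)]
    v + 1L
  }
  i1 <- idx_of(s1$symbols)
  i2 <- idx_of(s2$symbols)
  counts <- matrix(0L, nw, nw, dimnames = list(labels, labels))
  tab <- table(factor(i1, levels = seq_len(nw)),
               factor(i2, levels = seq_len(nw)))
  counts[] <- as.integer(tab)
  total <- sum(counts)
  structure(list(counts = counts, probs = counts / total, word_length = k,
                 alphabet_size = a),
            class = "joint_word_matrix")
}

#' Family of a ternary length-3 word
#'
#' @param word character word over \{0,1,2\} of length 3, e.g. `"202"`.
#' @return The family label (see [hrjsd_families()]).
#' @export
#' @examples
#' family_of("000")  # "E0"
#' family_of("202")  # "LA1"
family_of <- function(word) {
  fam <- hrjsd_families()
  if (any(!word %in% names(fam)))
    stop(sprintf("not a ternary length-3 word: %s",
                 paste(setdiff(word, names(fam)), collapse = ", ")),
         call. = FALSE)
  unname(fam[word])
}

#' Group a ternary joint word matrix into pattern families
#'
#' Sums the 27 x 27 joint word probabilities over the family membership of
#' each word, giving the 8 x 8 family matrix, its row/column marginals, and
#' the Shannon entropy (bits) of the 64-cell family distribution.
#'
#' @param m a ternary [joint_word_distribution()] result.
#' @return An object of class `family_matrix`: `probs` (8 x 8), `counts`,
#'   `marginals_ch1`, `marginals_ch2` (8-vectors), `entropy` (bits).
#' @export
family_distribution <- function(m) {
  stopifnot(inherits(m, "joint_word_matrix"))
  if (m$alphabet_size != 3L || nrow(m$probs) != 27L)
    stop("family grouping is defined for the 27 x 27 ternary matrix",
         call. = FALSE)
  fam <- factor(family_of(rownames(m$probs)), levels = family_levels())
  agg <- function(mat) {
    out <- rowsum(t(rowsum(mat, fam)), fam)  # group columns then rows
    t(out)[family_levels(), family_levels()]
  }
  probs <- agg(m$probs)
  counts <- agg(m$counts + 0)
  p <- probs[probs > 0]
  structure(list(probs = probs, counts = counts,
                 marginals_ch1 = rowSums(probs),
                 marginals_ch2 = colSums(probs),
                 entropy = -sum(p * log2(p))),
            class = "family_matrix")
}

#' HRJSD feature vector for one channel pair
#'
#' Emits, for a coupling tag `xy` (e.g. `"cs"` with channel letters `c` and
#' `s`), the 64 family-cell probabilities `HRJSDxy_F1-F2`, the 8 + 8 family
#' marginals `HRJSDxy-Fc` / `HRJSDxy-Fs`, and the joint Shannon entropy
#' `HRJSDShxy` (81 indices).
#'
#' @param x1,x2 beat-value sequences of the two channels.
#' @param tag two-letter coupling tag, e.g. `"cs"`, `"cd"`, `"ds"`.
#' @param l1,l2 symbolization thresholds for the two channels.
#' @return Named numeric vector of 81 features.
#' @export
hrjsd_features <- function(x1, x2, tag, l1, l2) {
  s1 <- symbolize(x1, "ternary", l1)
  s2 <- symbolize(x2, "ternary", l2)
  fm <- family_distribution(joint_word_distribution(s1, s2))
  ch <- strsplit(tag, "")[[1]]
  cells <- as.vector(t(fm$probs))  # row-major: F1 outer, F2 inner
  cell_names <- as.vector(t(outer(family_levels(), family_levels(),
                                  function(a, b) paste0(a, "-", b))))
  out <- c(cells, fm$marginals_ch1, fm$marginals_ch2, fm$entropy)
  names(out) <- c(paste0("HRJSD", tag, "_", cell_names),
                  paste0("HRJSD", tag, "-", family_levels(), ch[1]),
                  paste0("HRJSD", tag, "-", family_levels(), ch[2]),
                  paste0("HRJSDSh", tag))
  out
}

#' Binary JSD feature vector for one channel pair
#'
#' Emits the 64 joint word probabilities of the 8 x 8 binary word matrix,
#' named `JSDxy_w1-w2`, plus the joint Shannon entropy `JSDShxy`.
#'
#' @inheritParams hrjsd_features
#' @return Named numeric vector of 65 features.
#' @export
jsd_features <- function(x1, x2, tag) {
  s1 <- symbolize(x1, "binary")
  s2 <- symbolize(x2, "binary")
  m <- joint_word_distribution(s1, s2)
  p <- m$probs[m$probs > 0]
  vals <- c(as.vector(t(m$probs)), -sum(p * log2(p)))
  nm <- as.vector(t(outer(rownames(m$probs), colnames(m$probs),
                          function(a, b) paste0(a, "-", b))))
  names(vals) <- c(paste0("JSD", tag, "_", nm), paste0("JSDSh", tag))
  vals
}
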