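#' Grantham amino-acid distance matrix
#'
#' Regenerated from the 1974 side-chain property values: composition c,
#' polarity p and molecular volume v, combined as
#' `d = 50.723 * sqrt(1.833 (dc)^2 + 0.1018 (dp)^2 + 0.000399 (dv)^2)`
#' and rounded to integers as conventionally published (the scale constant
#' normalises the mean over all pairs to about 100).
#'
#' @param rounded return integer-rounded distances (default TRUE).
#' @return symmetric 20 x 20 matrix with zero diagonal, rows/columns in
#'   1-letter amino-acid order.
#' @export
grantham_matrix <- function(rounded = TRUE) {
  props <- grantham_properties()
  aa <- rownames(props)
  dc <- outer(props[, "c"], props[, "c"], "-")
  dp <- outer(props[, "p"], props[, "p"], "-")
  dv <- outer(props[, "v"], props[, "v"], "-")
  d <- 50.723 * sqrt(1.833 * dc^2 + 0.1018 * dp^2 + 0.000399 * dv^2)
  dimnames(d) <- list(aa, aa)
  if (rounded) round(d) else d
}

#' Grantham 1974 side-chain properties
#' @return matrix with rows = amino acids (1-letter), columns `c`
#'   (composition), `p` (polarity), `v` (volume).
#' @export
grantham_properties <- function() {
  m <- rbind(
    A = c(0.00, 8.1, 31), R = c(0.65, 10.5, 124), N = c(1.33, 11.6, 56),
    D = c(1.38, 13.0, 54), C = c(2.75, 5.5, 55), Q = c(0.89, 10.5, 85),
    E = c(0.92, 12.3, 83), G = c(0.74, 9.0, 3), H = c(0.58, 10.4, 96),
    I = c(0.00, 5.2, 111), L = c(0.00, 4.9, 111), K = c(0.33, 11.3, 119),
    M = c(0.00, 5.7, 105), F = c(0.00, 5.2, 132), P = c(0.39, 8.0, 32.5),
    S = c(1.42, 9.2, 32), T = c(0.71, 8.6, 61), W = c(0.13, 5.4, 170),
    Y = c(0.20, 6.2, 136), V = c(0.00, 5.9, 84)
  )
  colnames(m) <- c("c", "p", "v")
  m
}

#' Grantham distance between two amino acids
#'
#' @param aa1,aa2 1-letter amino-acid codes (standard 20 only; gaps and
#'   nonstandard codes are an error — callers handle gap policy).
#' @return distance (integer-rounded).
#' @export
grantham_distance <- function(aa1, aa2) {
  g <- grantham_matrix()
  if (!(aa1 %in% rownames(g)) || !(aa2 %in% rownames(g))) {
    stop("grantham_distance is defined for standard amino acids only, got '",
         aa1, "', '", aa2, "'")
  }
  g[aa1, aa2]
}

#' Pair counts within and between two groups
#'
#' @param n_low,n_high group sizes.
#' @return named vector `c(intra_low, intra_high, inter)` =
#'   (C(n_low,2), C(n_high,2), n_low*n_high).
#' @export
group_pair_counts <- function(n_low, n_high) {
  stopifnot(n_low >= 0, n_high >= 0)
  c(intra_low = choose(n_low, 2), intra_high = choose(n_high, 2),
    inter = n_low * n_high)
}

#' Residual inter-group Grantham distance along an alignment
#'
#' At every alignment column, mean Grantham distances are computed over all
#' intra-low, intra-high and inter-group sequence pairs (pairs touching a
#' gap or nonstandard residue are dropped). The residual is the inter-group
#' mean minus the greater of the two intra-group means. Columns where more
#' than half of the inter-group pairs are undefined (gap-dominated) get a
#' residual of 0 and a `gap_dominated` flag. Columns whose residual exceeds
#' mean + 3*SD (over columns) are flagged.
#'
#' @param alignment a [read_alignment()] data.frame.
#' @param low_ids,high_ids sequence ids of the two groups (must partition
#'   into disjoint sets).
#' @return data.frame of class `residual_profile` with per-column `inter`,
#'   `intra_low`, `intra_high`, `residual`, `gap_dominated`, `flag`.
#' @export
residual_profile <- function(alignment, low_ids, high_ids) {
  if (length(intersect(low_ids, high_ids))) {
    stop("a sequence cannot be in both groups")
  }
  miss <- setdiff(c(low_ids, high_ids), alignment$id)
  if (length(miss)) stop("ids not in alignment: ", paste(miss, collapse = ", "))
  g <- grantham_matrix()
  seqs <- strsplit(alignment$seq, "")
  names(seqs) <- alignment$id
  ncol_aln <- length(seqs[[1]])
  lo <- seqs[low_ids]; hi <- seqs[high_ids]
  aa_ok <- rownames(g)
  pair_mean <- function(set_a, set_b, col) {
    # intra-group when set_b is NULL
    pairs <- if (is.null(set_b)) {
      if (length(set_a) < 2) list()
      else utils::combn(length(set_a), 2, simplify = FALSE)
    } else {
      do.call(c, lapply(seq_along(set_a), function(i) {
        lapply(seq_along(set_b), function(j) c(i, j))
      }))
    }
    vals <- numeric(0); dropped <- 0L
    for (pp in pairs) {
      a <- set_a[[pp[1]]][col]
      b <- if (is.null(set_b)) set_a[[pp[2]]][col] else set_b[[pp[2]]][col]
      if (a %in% aa_ok && b %in% aa_ok) vals <- c(vals, g[a, b])
      else dropped <- dropped + 1L
    }
    list(mean = if (length(vals)) mean(vals) else NA_real_,
         dropped = dropped, total = length(pairs))
  }
  out <- data.frame(column = seq_len(ncol_aln), inter = NA_real_,
                    intra_low = NA_real_, intra_high = NA_real_,
                    residual = 0, gap_dominated = FALSE)
  for (col in seq_len(ncol_aln)) {
    il <- pair_mean(lo, NULL, col)
    ih <- pair_mean(hi, NULL, col)
    xx <- pair_mean(lo, hi, col)
    out$inter[col] <- xx$mean
    out$intra_low[col] <- il$mean
    out$intra_high[col] <- ih$mean
    if (xx$dropped > xx$total / 2 || is.na(xx$mean) ||
        (is.na(il$mean) && is.na(ih$mean))) {
      out$residual[col] <- 0
      out$gap_dominated[col] <- TRUE
    } else {
      intra_max <- max(c(il$mean, ih$mean), na.rm = TRUE)
      out$residual[col] <- xx$mean - intra_max
    }
  }
  m <- mean(out$residual); s <- stats::sd(out$residual)
  out$flag <- out$residual > m + 3 * s
  class(out) <- c("residual_profile", "data.frame")
  out
}
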