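# Independent brute-force oracles, written as literal translations of the
# metric definitions. They deliberately share no code with the package:
# explicit double loops over every pair, no packing tricks.

oracle_nodf <- function(x) {
  b <- (x > 0) * 1
  b <- b[order(-rowSums(b)), order(-colSums(b)), drop = FALSE]
  row_sum <- 0
  nr <- nrow(b)
  for (i in seq_len(nr - 1)) {
    for (j in seq(i + 1, nr)) {
      mti <- sum(b[i, ]); mtj <- sum(b[j, ])
      if (mti > mtj && mtj > 0) {
        row_sum <- row_sum + 100 * sum(b[i, ] == 1 & b[j, ] == 1) / mtj
      }
    }
  }
  col_sum <- 0
  nc <- ncol(b)
  for (l in seq_len(nc - 1)) {
    for (r in seq(l + 1, nc)) {
      mtl <- sum(b[, l]); mtr <- sum(b[, r])
      if (mtl > mtr && mtr > 0) {
        col_sum <- col_sum + 100 * sum(b[, l] == 1 & b[, r] == 1) / mtr
      }
    }
  }
  list(
    overall = (row_sum + col_sum) / (choose(nr, 2) + choose(nc, 2)),
    row = row_sum / choose(nr, 2),
    col = col_sum / choose(nc, 2)
  )
}

oracle_wnodf <- function(x) {
  x <- x[order(-rowSums(x)), order(-colSums(x)), drop = FALSE]
  row_sum <- 0
  nr <- nrow(x)
  for (i in seq_len(nr - 1)) {
    for (j in seq(i + 1, nr)) {
      fillj <- sum(x[j, ] > 0)
      if (sum(x[i, ]) > sum(x[j, ]) && fillj > 0) {
        cnt <- 0
        for (c in seq_len(ncol(x))) {
          if (x[j, c] > 0 && x[i, c] > x[j, c]) cnt <- cnt + 1
        }
        row_sum <- row_sum + 100 * cnt / fillj
      }
    }
  }
  col_sum <- 0
  nc <- ncol(x)
  for (l in seq_len(nc - 1)) {
    for (r in seq(l + 1, nc)) {
      fillr <- sum(x[, r] > 0)
      if (sum(x[, l]) > sum(x[, r]) && fillr > 0) {
        cnt <- 0
        for (k in seq_len(nrow(x))) {
          if (x[k, r] > 0 && x[k, l] > x[k, r]) cnt <- cnt + 1
        }
        col_sum <- col_sum + 100 * cnt / fillr
      }
    }
  }
  list(
    overall = (row_sum + col_sum) / (choose(nr, 2) + choose(nc, 2)),
    row = row_sum / choose(nr, 2),
    col = col_sum / choose(nc, 2)
  )
}

# Exact expected rarefied richness by enumerating every m-subset of
# individuals (tiny n only).
oracle_rarefaction <- function(x, m) {
  individuals <- rep(seq_along(x), x)
  subsets <- utils::combn(length(individuals), m)
  mean(apply(subsets, 2, function(idx) length(unique(individuals[idx]))))
}

random_community <- function(nr, nc, lambda = 1.5) {
  x <- matrix(stats::rpois(nr * nc, lambda), nr, nc,
    dimnames = list(sprintf("r%02d", seq_len(nr)), sprintf("c%02d", seq_len(nc)))
  )
  # keep at least one presence per margin size requirement
  if (all(x == 0)) x[1, 1] <- 1L
  storage.mode(x) <- "integer"
  x
}

toy_matrix <- function(cells, nr, species = NULL, sites = NULL, byrow = TRUE) {
  m <- matrix(as.integer(cells), nrow = nr, byrow = byrow)
  rownames(m) <- if (is.null(species)) sprintf("sp%d", seq_len(nrow(m))) else species
  colnames(m) <- if (is.null(sites)) sprintf("s%d", seq_len(ncol(m))) else sites
  m
}

toy_groups <- function(species,
                       passerine = rep(TRUE, length(species)),
                       resident = rep(TRUE, length(species)),
                       guild = rep("insectivorous", length(species)),
                       waterbird = rep(FALSE, length(species))) {
  tibble::tibble(
    species_id = species, is_passerine = passerine, is_resident = resident,
    diet_guild = guild, is_waterbird = waterbird
  )
}
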