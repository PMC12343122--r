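align_partitions <- function(a, b) {
  la <- if (is.list(a) && !is.null(a$labels)) a$labels else a
  lb <- if (is.list(b) && !is.null(b$labels)) b$labels else b
  if (inherits(a, "chase")) la <- a$best$labels
  if (inherits(b, "chase")) lb <- b$best$labels
  if (!is.null(names(la)) && !is.null(names(lb))) {
    if (!setequal(names(la), names(lb))) {
      diff <- c(setdiff(names(la), names(lb)), setdiff(names(lb), names(la)))
      stop("partitions cover different site sets; differing sites: ",
           paste(lex_sort(diff), collapse = ", "))
    }
    lb <- lb[names(la)]
  } else if (length(la) != length(lb)) {
    stop("partitions cover different numbers of sites")
  }
  list(a = as.integer(factor(la)), b = as.integer(factor(lb)),
       sites = names(la))
}

#' Cross-tabulate two partitions of the same sites
#'
#' @param a,b partitions: label vectors (named by site id when available),
#'   `chase` fits, or `ward_geo` fits.
#' @return contingency table (rows: clusters of `a`, columns: clusters of
#'   `b`).
#' @export
contingency <- function(a, b) {
  al <- align_partitions(a, b)
  table(A = al$a, B = al$b)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#'   E = \frac{\sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2}}{\binom{n}{2}}}
#' where n_ij is the contingency table and a_i, b_j its margins. 1 means
#' identical partitions; independent random partitions score near 0;
#' values below 0 indicate less agreement than chance. When the
#' denominator vanishes (both partitions trivial) the index is undefined;
#' we return 1 if the partitions are identical and 0 otherwise.
#'
#' @inheritParams contingency
#' @return a number <= 1.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
adjusted_rand_index <- function(a, b) {
  al <- align_partitions(a, b)
  ct <- table(al$a, al$b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(if (all(al$a == al$b)) 1 else 0)
  (sum_ij - expected) / denom
}

#' Partition agreement report
#'
#' Bundles the adjusted Rand index, the contingency table, and the
#' best-matching cluster pairs (maximum-overlap one-to-one matching) into
#' one object, for comparisons such as wild-only vs with-domesticates or
#' chase vs constrained Ward.
#'
#' @inheritParams contingency
#' @return object of class `partition_comparison`.
#' @export
compare_partitions <- function(a, b) {
  ct <- contingency(a, b)
  m <- match_clusters(ct)
  matches <- data.frame(cluster_a = seq_len(nrow(ct)),
                        cluster_b = m,
                        overlap = vapply(seq_len(nrow(ct)), function(i)
                          if (is.na(m[i])) 0L else as.integer(ct[i, m[i]]),
                          integer(1)))
  structure(list(ari = adjusted_rand_index(a, b), contingency = ct,
                 matches = matches),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("Partition comparison: ARI = %.3f\n", x$ari))
  cat("Contingency table (rows A, columns B):\n")
  print(x$contingency)
  cat("Best one-to-one cluster matches (A -> B, shared sites):\n")
  print(x$matches, row.names = FALSE)
  invisible(x)
}
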