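# Cross-validation fold plans: the held-out test set is fixed by the cohort
# split; non-test subjects are partitioned into K validation blocks, each
# fold training on the remaining non-test subjects.

#' Build a k-fold cross-validation plan
#'
#' Partitions the non-test cohort into `K` near-equal validation blocks
#' (sizes differ by at most one) after a seeded shuffle. Each fold's
#' training set is the complement of its validation block within the
#' non-test cohort; the test set is fixed across folds.
#'
#' @param cohort cohort table with `id` and `split` columns.
#' @param K number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return A `taucl_fold_plan`: list with `K`, `test` (ids), and `folds`,
#'   a list of `K` lists each holding `train` and `validation` id vectors.
#' @export
make_folds <- function(cohort, K = 10L, seed = 1L) {
  K <- as.integer(K)
  test_ids <- cohort$id[cohort$split == "test"]
  pool <- cohort$id[cohort$split != "test"]
  n <- length(pool)
  if (K < 1L || K > n)
    stop(sprintf("K = %d folds but only %d non-test subjects", K, n))
  shuffled <- with_seed(derive_seed(seed, "folds"), sample(pool))
  block <- rep(seq_len(K), length.out = n)
  # sizes floor(n/K) or ceiling(n/K); contiguous blocks over the shuffle
  block <- sort(block)
  folds <- lapply(seq_len(K), function(k) {
    val <- shuffled[block == k]
    list(train = setdiff(pool, val), validation = val)
  })
  structure(list(K = K, test = test_ids, folds = folds),
            class = "taucl_fold_plan")
}

#' @export
print.taucl_fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$validation), integer(1))
  cat(sprintf(
    "<taucl_fold_plan> K = %d, validation blocks of %s, %d test subjects\n",
    x$K, paste(sort(unique(sizes)), collapse = "/"), length(x$test)))
  invisible(x)
}
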