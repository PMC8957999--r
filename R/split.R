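# Per-surgeon random 70/30 train/test split.

#' Split a dataset into per-surgeon training and test sets
#'
#' Each surgeon's cases are split independently and reproducibly:
#' `round(0.7 n)` training cases, the rest test.
#'
#' @param cases a `tka_dataset`.
#' @param seed integer seed.
#' @param train_fraction training fraction (default 0.7).
#' @return An object of class `split_spec`: per surgeon, the training and
#'   test case IDs.
#' @export
split_dataset <- function(cases, seed = 1L, train_fraction = 0.7) {
  surgeons <- dataset_surgeons(cases)
  spec <- lapply(surgeons, function(s) {
    ids <- vapply(Filter(function(cs) cs$surgeon == s, cases), `[[`, "", "case_id")
    n <- length(ids)
    if (n < 10L) stop("surgeon ", s, " has fewer than 10 cases")
    n_train <- round(train_fraction * n)
    tr <- with_seed(seed_stream(seed, paste0("split-", s)),
                    sample(ids, n_train))
    list(train = sort(tr), test = sort(setdiff(ids, tr)))
  })
  names(spec) <- surgeons
  structure(list(surgeons = spec, seed = seed,
                 train_fraction = train_fraction), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  for (s in names(x$surgeons))
    cat(s, ": ", length(x$surgeons[[s]]$train), " train / ",
        length(x$surgeons[[s]]$test), " test\n", sep = "")
  invisible(x)
}

split_cases <- function(cases, split, surgeon, part = c("train", "test")) {
  part <- match.arg(part)
  ids <- split$surgeons[[surgeon]][[part]]
  structure(Filter(function(cs) cs$case_id %in% ids, cases),
            class = "tka_dataset")
}
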