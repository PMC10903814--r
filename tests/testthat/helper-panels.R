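# Builders for small panels used across the tests.

# Single- or multi-period panel from m x n input and q x n output matrices.
# Xs/Ys: named lists (period -> matrix) or single matrices (one period "1").
panel_from_mats <- function(Xs, Ys) {
  if (is.matrix(Xs)) Xs <- list(`1` = Xs)
  if (is.matrix(Ys)) Ys <- list(`1` = Ys)
  m <- nrow(Xs[[1]])
  q <- nrow(Ys[[1]])
  n <- ncol(Xs[[1]])
  dmus <- if (!is.null(colnames(Xs[[1]]))) colnames(Xs[[1]]) else LETTERS[seq_len(n)]
  rows <- list()
  for (p in names(Xs)) {
    df <- data.frame(dmu = dmus, period = p, stringsAsFactors = FALSE)
    for (i in seq_len(m)) df[[paste0("x", i)]] <- Xs[[p]][i, ]
    for (r in seq_len(q)) df[[paste0("y", r)]] <- Ys[[p]][r, ]
    rows[[p]] <- df
  }
  panel_dataset(do.call(rbind, rows),
                inputs = paste0("x", seq_len(m)),
                outputs = paste0("y", seq_len(q)))
}

# The two-unit toy: A = (x 1, y 1) efficient, B = (x 2, y 1) inefficient.
toy_pair <- function() {
  panel_from_mats(matrix(c(1, 2), 1, dimnames = list(NULL, c("A", "B"))),
                  matrix(c(1, 1), 1, dimnames = list(NULL, c("A", "B"))))
}

random_instance <- function(n, m, q) {
  list(X = matrix(exp(stats::rnorm(m * n, 0, 0.6)), m),
       Y = matrix(exp(stats::rnorm(q * n, 0, 0.6)), q))
}
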