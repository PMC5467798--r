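# Build a small CRT dataset by hand from per-cluster outcome vectors.
# values: list of two lists (one per arm), each a list of numeric vectors of
# cluster outcomes; NA marks an unobserved outcome (r = 0, true y retained as
# the NA placeholder is replaced by `hidden`).
make_crt <- function(values, x = NULL, hidden = 0) {
  rows <- list()
  for (arm in 1:2) {
    for (j in seq_along(values[[arm]])) {
      v <- values[[arm]][[j]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        arm = arm, cluster = j, individual = seq_along(v),
        x = 0, y = ifelse(is.na(v), hidden, v), r = as.integer(!is.na(v))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(x)) out$x <- x
  out
}

# ANOVA moment estimator of the ICC on balanced complete data (oracle for
# checking the generator's clustering structure).
anova_icc <- function(data) {
  cl <- dplyr::summarise(dplyr::group_by(data, arm, cluster),
                         m = dplyr::n(), ybar = mean(y), .groups = "drop")
  m <- cl$m[1]
  J <- nrow(cl)
  ybar_arm <- tapply(data$y, data$arm, mean)
  msb <- sum(cl$m * (cl$ybar - ybar_arm[cl$arm])^2) / (J - 2)
  grp <- paste(data$arm, data$cluster)
  msw <- sum((data$y - ave(data$y, grp))^2) / (nrow(data) - J)
  (msb - msw) / (msb + (m - 1) * msw)
}
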