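# Shared fixture builders; everything is generated in code at test time.

# Two-view measurement tibble with chosen CNRs and times.
make_measurements <- function(cnr = c(0.10, 0.05), times = c(120, 224),
                              views = c("CC", "MLO"), sb = 100) {
  tibble::tibble(view = views, time = times,
                 sa = sb * (1 + cnr), sb = sb, cnr = cnr)
}

# Uniform-background test image with a brighter square lesion.
make_image_fixture <- function(bg = 100, lesion_max = 110, n = 16) {
  img <- matrix(bg, n, n)
  les <- matrix(FALSE, n, n)
  les[6:10, 6:10] <- TRUE
  img[8, 8] <- lesion_max
  bgm <- !les
  list(image = img, lesion = les, background = bgm)
}

# Random k x k count table with positive total.
random_table <- function(k, max_count = 30) {
  matrix(sample.int(max_count + 1, k * k, replace = TRUE) - 1L, k, k) +
    diag(1, k)  # keep the total positive and the diagonal occupied
}

# Scored-cohort rows whose CNR pairs realise a requested pattern mix.
# Patterns map to canonical pairs: ascending (1, 2), steady (1, 1),
# descending (2, 1), none (0, 0).
cohort_from_patterns <- function(n_by_pattern, pathology) {
  pair_for <- list(ascending = c(1, 2), steady = c(1, 1),
                   descending = c(2, 1), none = c(0, 0))
  rows <- purrr::imap(n_by_pattern, function(n, p) {
    tibble::tibble(cnr1 = rep(pair_for[[p]][1], n),
                   cnr2 = rep(pair_for[[p]][2], n))
  })
  out <- dplyr::bind_rows(rows)
  out$pathology <- pathology
  out$lesion_id <- sprintf("X%03d", seq_len(nrow(out)))
  out
}
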