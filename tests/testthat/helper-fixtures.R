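# direct constructor for a Gaussian class model, bypassing fitting, so the
# classifier math can be tested against closed forms
make_model <- function(mu_a, sigma_a, mu_b, sigma_b,
                       prior_a = 0.5, n_a = 10L, n_b = 10L,
                       class_a = "nonNE", class_b = "NE") {
  structure(
    list(class_a = class_a, class_b = class_b,
         mu_a = mu_a, mu_b = mu_b, sigma_a = sigma_a, sigma_b = sigma_b,
         prior_a = prior_a, prior_b = 1 - prior_a, n_a = n_a, n_b = n_b),
    class = "gaussian_class_model"
  )
}

# hand-built raw Ct table: one row per replicate from a named list
# sample -> assay -> c(ct1, ct2, ct3)
make_ct_table <- function(samples, classes = NULL, subtypes = NULL) {
  purrr::imap_dfr(samples, function(assays, sid) {
    purrr::imap_dfr(assays, function(cts, a) {
      tibble::tibble(
        sample_id = sid,
        subtype = (subtypes %||% setNames(rep("AD", length(samples)),
                                          names(samples)))[[sid]],
        class = (classes %||% setNames(rep("nonNE", length(samples)),
                                       names(samples)))[[sid]],
        stage = NA_character_,
        assay = a, replicate = seq_along(cts), ct = cts
      )
    })
  })
}

`%||%` <- rlang::`%||%`

# drop generator bookkeeping attributes so data-frame contents can be
# compared across an I/O round trip
plain_df <- function(x) {
  x <- as.data.frame(x)
  keep <- c("names", "row.names", "class")
  attributes(x)[setdiff(names(attributes(x)), keep)] <- NULL
  x
}

# cohort spec with tight, well-separated classes and no technical noise:
# every downstream stage becomes exactly checkable
zero_noise_spec <- function(n = c(nonNE = 10, NE = 10), seed = 1,
                            sigma_dct = c(nonNE = 0, NE = 0),
                            mu_dct = c(nonNE = 0.9, NE = 5.8)) {
  cohort_spec(n_per_class = n, mu_dct = mu_dct, sigma_dct = sigma_dct,
              sigma_u6 = 0, sigma_tech = 0, seed = seed)
}
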