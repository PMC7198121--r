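# Independent brute-force oracles and small fixture builders, kept free of
# the package's own code paths so they can validate them.

# Dice by explicit position-by-position loop.
dice_loop <- function(f1, f2) {
  h <- 0L; a <- 0L; b <- 0L
  for (i in seq_along(f1)) {
    if (f1[i] == 1L) a <- a + 1L
    if (f2[i] == 1L) b <- b + 1L
    if (f1[i] == 1L && f2[i] == 1L) h <- h + 1L
  }
  if (a + b == 0L) 0L else as.integer(floor(2 * h / (a + b) * 10000 + 0.5))
}

# Candidate pairs by exhaustive double loop over the cross product,
# checking exact agreement on the non-missing attributes of each clause.
exhaustive_candidate_pairs <- function(ha, hb) {
  clause1 <- c("name", "mother_name", "municipality_code")
  clause2 <- c("surname", "mother_surname", "year_of_birth")
  agrees <- function(ra, rb, fields) {
    all(vapply(fields, function(f) {
      nzchar(ra[[f]]) && nzchar(rb[[f]]) && ra[[f]] == rb[[f]]
    }, logical(1)))
  }
  rows <- list()
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(nrow(hb))) {
      c1 <- agrees(ha[i, ], hb[j, ], clause1)
      c2 <- agrees(ha[i, ], hb[j, ], clause2)
      if (c1 || c2) {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ha$record_id[i], id_b = hb$record_id[j],
          via = paste(which(c(c1, c2)), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id_a = character(0), id_b = character(0), via = character(0))
  }
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

# Best Youden cutoff by exhaustive search over the grid.
best_cutoff_loop <- function(scores, truth, grid) {
  best_j <- -Inf; best_t <- NA_integer_
  for (t in sort(grid)) {
    tp <- sum(scores >= t & truth)
    fp <- sum(scores >= t & !truth)
    sens <- tp / sum(truth)
    fpr <- if (sum(!truth) == 0) 0 else fp / sum(!truth)
    j <- sens - fpr
    if (j >= best_j) { best_j <- j; best_t <- t }
  }
  best_t
}

# A harmonized record built directly from clean values.
make_harmonized <- function(id, name = "JOSE DA SILVA",
                            mother = "MARIA LUZIA SILVA",
                            dob = "19850312", gender = "M",
                            muni = "2912345") {
  harmonize_records(data.frame(
    record_id = id, name = name, mother_name = mother,
    date_of_birth = if (nzchar(dob)) {
      paste(substr(dob, 1, 4), substr(dob, 5, 6), substr(dob, 7, 8),
            sep = "-")
    } else "",
    gender = gender, municipality_code = muni,
    stringsAsFactors = FALSE))
}

# Mean fraction of accepted pairs that are gold-true, for one synthetic run.
run_ppv_pct <- function(n, corruption, n_noise = round(0.2 * n),
                        mode = "hybrid") {
  syn <- generate_cohort(n, 1, corruption, n_noise = n_noise)
  cfg <- pipeline_config(mode = mode)
  res <- suppressWarnings(
    run_pipeline(syn$file_a, syn$file_b, cfg, gold = syn$gold,
                 verbose = FALSE))
  gk <- paste(syn$gold$id_a, syn$gold$id_b)
  mk <- paste(res$matches$id_a, res$matches$id_b)
  list(pct_true = 100 * mean(mk %in% gk), report = res$report,
       result = res, gold = syn$gold)
}
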