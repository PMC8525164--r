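test_that("table loading normalizes, deduplicates and validates schema", {
  df <- toy_association_df()
  # exact duplicate and sloppy whitespace collapse to the same record
  df2 <- rbind(df, data.frame(
    fly_species = "Fly  a", host_species = " Cucumis   sativus ",
    host_genus = "Cucumis", host_family = "Cucurbitaceae"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path, row.names = FALSE)
  expect_message(tab <- load_association_table(path), "1 duplicate")
  expect_equal(nrow(tab), nrow(df))
  expect_true(all(tab$status == "valid"))

  # missing column is a schema error
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -4], path2, row.names = FALSE)
  expect_error(load_association_table(path2), "host_family")

  # empty required field is rejected with the row number
  df3 <- df
  df3$host_family[5] <- ""
  expect_error(association_table(df3), "row\\(s\\): 5")

  # a species under two families is a consistency error naming the genus
  df4 <- rbind(df, data.frame(
    fly_species = "Fly c", host_species = "Cucumis oddball",
    host_genus = "Cucumis", host_family = "Rosaceae"))
  expect_error(association_table(df4), "Cucumis")

  # excluded records are retained but inert
  df5 <- df
  df5$status <- c(rep("valid", 5), "excluded_doubtful")
  tab5 <- association_table(df5)
  expect_equal(nrow(tab5), 6)
  expect_false("Fly c" %in% host_breadth(tab5)$fly_species)
})

test_that("host breadth counts species, genera and families per fly", {
  tab <- association_table(toy_association_df())
  prof <- host_breadth(tab)
  a <- prof[prof$fly_species == "Fly a", ]
  expect_equal(a$n_host_species, 3)
  expect_equal(a$n_host_genera, 2)
  expect_equal(a$n_host_families, 2)
  expect_true(all(prof$n_host_families <= prof$n_host_genera))
  expect_true(all(prof$n_host_genera <= prof$n_host_species))

  # worked percentages: 8/37 monophages, 11/37 extreme polyphages
  expect_equal(round(100 * 8 / 37, 2), 21.62)
  expect_equal(round(100 * 11 / 37, 2), 29.73)
})

test_that("polyphagy binarization is strict and monotone in the threshold", {
  prof <- data.frame(fly_species = paste0("f", 1:5),
                     n_host_species = 1:5, n_host_genera = 1:5,
                     n_host_families = 1:5)
  class(prof) <- c("breadth_profile", "data.frame")
  b2 <- binarize_polyphagy(prof, 2)
  expect_equal(unname(b2$trait), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(b2$n_polyphagous, 3)
  expect_equal(binarize_polyphagy(prof, 3)$n_polyphagous, 2)
  counts <- vapply(1:5, function(th)
    binarize_polyphagy(prof, th)$n_polyphagous, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("interaction matrix recovers a known generating matrix", {
  tab <- association_table(toy_association_df())
  m <- interaction_matrix(tab)
  expect_equal(m["Fly a", c("Citrus", "Cucumis")], c(Citrus = 1L, Cucumis = 1L))
  expect_equal(m["Fly c", "Citrus"], 0L)
  v <- tab[tab$status == "valid", ]
  expect_equal(sum(m), nrow(unique(v[, c("fly_species", "host_genus")])))
  expect_equal(unname(rowSums(m)),
               host_breadth(tab)$n_host_genera[
                 match(rownames(m), host_breadth(tab)$fly_species)])

  # generator round-trip: matrix of the synthetic system matches its table
  sys <- simulate_association_system(n_flies = 8, n_genera = 30,
                                     n_families = 6, seed = 12)
  m2 <- interaction_matrix(sys$table)
  v2 <- sys$table[sys$table$status == "valid", ]
  for (f in rownames(m2))
    expect_setequal(colnames(m2)[m2[f, ] == 1L],
                    unique(v2$host_genus[v2$fly_species == f]))
})

test_that("DEC filtering drops extreme polyphages and named exclusions", {
  # 37 flies: 11 with >= 20 families, one monophage excluded by name -> 25
  set.seed(40)
  recs <- list()
  for (i in 1:37) {
    nf <- if (i <= 11) 20 + (i %% 5) else if (i <= 19) 1 else 2 + (i %% 15)
    fams <- paste0("Fam", seq_len(nf))
    recs[[i]] <- data.frame(
      fly_species = sprintf("fly%02d", i),
      host_species = paste0("Genus", seq_len(nf), "_f", i, " sp"),
      host_genus = paste0("Genus", seq_len(nf), "_f", i),
      host_family = fams)
  }
  tab <- association_table(do.call(rbind, recs))
  flt <- filter_for_dec(tab, max_families = 20, exclude = "fly12")
  expect_length(flt$retained, 25)
  expect_false(any(c("fly01", "fly12") %in% flt$retained))

  # identity when nothing is filtered
  flt2 <- filter_for_dec(tab, max_families = Inf)
  expect_length(flt2$retained, 37)
  expect_warning(filter_for_dec(tab, max_families = 1), "empty")
  expect_warning(filter_for_dec(tab, exclude = "no such fly"), "not present")
})

test_that("main host families rank correctly with alphabetical tie-break", {
  recs <- data.frame(
    fly_species = "f1",
    host_species = c(paste0("Cuc sp", 1:4), paste0("Rut sp", 1:3),
                     paste0("Ros sp", 1:3)),
    host_genus = c(rep("Cucumis", 4), rep("Citrus", 3), rep("Rosa", 3)),
    host_family = c(rep("Cucurbitaceae", 4), rep("Rutaceae", 3),
                    rep("Rosaceae", 3)))
  tab <- association_table(recs)
  expect_equal(main_host_families(tab, k = 1), "Cucurbitaceae")
  expect_message(top2 <- main_host_families(tab, k = 2), "tie")
  expect_equal(top2, c("Cucurbitaceae", "Rosaceae"))
  expect_error(main_host_families(tab, k = 10), "exceeds")
  # ranking by fly species counts flies, not hosts
  expect_equal(main_host_families(tab, k = 1, rank_by = "n_fly_species"),
               "Cucurbitaceae")
})

test_that("tip range states intersect diets with the family list", {
  tab <- association_table(toy_association_df())
  st <- tip_range_states(tab, c("Cucurbitaceae", "Rutaceae"))
  expect_equal(st[["Fly c"]], "Cucurbitaceae")
  expect_setequal(st[["Fly a"]], c("Cucurbitaceae", "Rutaceae"))
  expect_error(tip_range_states(tab, "Rutaceae"), "Fly c")
  perm <- tip_range_states_permissive(tab, "Rutaceae")
  expect_length(perm[["Fly c"]], 0)
})

test_that("adding a valid record never decreases breadth counts", {
  base <- toy_association_df()
  tab0 <- association_table(base)
  p0 <- host_breadth(tab0)
  extra <- data.frame(fly_species = "Fly b", host_species = "Rosa canina",
                      host_genus = "Rosa", host_family = "Rosaceae")
  p1 <- host_breadth(association_table(rbind(base, extra)))
  for (col in c("n_host_species", "n_host_genera", "n_host_families"))
    expect_true(all(p1[[col]][match(p0$fly_species, p1$fly_species)] >=
                    p0[[col]]))
})
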