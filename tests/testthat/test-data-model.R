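test_that("length groups partition at the 33/34 and 38/39 cm boundaries", {
  expect_equal(as.character(assign_length_group(c(33, 36, 39))),
               c("S", "M", "L"))
  # sub-centimetre lengths partition at the same cut points
  expect_equal(as.character(assign_length_group(c(25, 33.9, 34, 38, 38.9))),
               c("S", "M", "M", "M", "L"))
  expect_error(assign_length_group(0), "positive")
  # every plausible adult length gets exactly one label
  lens <- seq(25, 50, by = 0.1)
  expect_false(anyNA(assign_length_group(lens)))
})

test_that("time periods are 6-hour half-open blocks of the local hour", {
  expect_equal(as.character(assign_time_period("2013-07-01 04:30:00")), "P1")
  expect_equal(as.character(assign_time_period("2013-07-01 12:00:00")), "P3")
  expect_equal(as.character(assign_time_period("2013-07-01 23:59:00")), "P4")
  expect_equal(as.character(assign_time_period("2013-07-01 05:59:59")), "P1")
  expect_equal(as.character(assign_time_period("2013-07-01 06:00:00")), "P2")
})

test_that("area assignment uses polygon precedence and warns outside", {
  polys <- default_area_polygons()
  expect_equal(assign_area(-21, 63.5, polys), "SW")
  expect_equal(assign_area(-27, 67, polys), "N")
  # shared N/E boundary at lat 66: N has precedence
  expect_equal(assign_area(-12, 66, polys), "N")
  # shared SE/SW edge at lon -19 inside both rectangles: SE wins (listed first)
  expect_equal(assign_area(-19, 63, polys), "SE")
  expect_warning(res <- assign_area(0, 0, polys), "outside")
  expect_equal(res, "unassigned")
})

test_that("Fulton's K follows 100 W / L^3", {
  expect_equal(fulton_k(1000, 10), 100)
  expect_equal(fulton_k(400, 36), 100 * 400 / 46656)
  expect_error(fulton_k(0, 30), "positive")
})

test_that("subsample expansion scales counts and weights by the volume ratio", {
  it <- item("copepods", 30, 0.04)
  out <- expand_subsample(it, 10, 2)
  expect_equal(out$count, 150)
  expect_equal(out$weight, 0.2)
  expect_equal(attr(out, "subsample_factor"), 5)
  expect_equal(expand_subsample(it, 2, 2)$count, it$count)
  expect_equal(expand_subsample(item("copepods", 8, 0.04), 8, 1)$weight, 0.32)
  expect_error(expand_subsample(it, 2, 0), "positive")
  expect_error(expand_subsample(it, 1, 2), "exceeds")
})

test_that("prey items validate and flag excluded categories", {
  expect_true(item("parasite", 1, 0.1)$excluded)
  expect_true(item("unidentified", 0, 0.3)$excluded)
  expect_false(item("copepods", 10, 0.1)$excluded)
  expect_error(prey_item("x", "copepods", -1, 1), "non-negative")
  expect_error(prey_item("x", "copepods", 0, 0), "both zero")
  expect_error(prey_item("x", "noodles", 1, 1))
})

test_that("a stomach holding only parasites counts as empty", {
  r <- fish("f1", items = list(item("parasite", 2, 0.5)))
  expect_true(r$is_empty)
  r2 <- fish("f2", items = list(item("parasite", 2, 0.5),
                                item("copepods", 5, 0.1)))
  expect_false(r2$is_empty)
  expect_error(fish("f3", len = 70), "plausibility")
})

test_that("stomach table read/write round-trips records exactly", {
  recs <- structure(list(
    fish("f1", items = list(item("copepods", 120.5, 0.31),
                            item("fish", 1, 4.2))),
    fish("f2", items = list(item("euphausiids", 3, 0.6))),
    fish("f3", items = list())), class = "stomach_records")
  path <- withr::local_tempfile(fileext = ".csv")
  write_stomach_table(recs, path)
  back <- read_stomach_table(path)
  expect_length(back, 3)
  expect_length(back[[1]]$items, 2)
  expect_true(back[[3]]$is_empty)
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$fish_id, recs[[i]]$fish_id)
    expect_equal(back[[i]]$length, recs[[i]]$length, tolerance = 1e-12)
    expect_equal(back[[i]]$stomach_weight, recs[[i]]$stomach_weight,
                 tolerance = 1e-12)
    for (j in seq_along(recs[[i]]$items)) {
      expect_equal(back[[i]]$items[[j]]$count, recs[[i]]$items[[j]]$count,
                   tolerance = 1e-12)
      expect_equal(back[[i]]$items[[j]]$weight, recs[[i]]$items[[j]]$weight,
                   tolerance = 1e-12)
    }
  }
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_stomach_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reader reports structural problems precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,station_id,length,body_weight,taxon_name,prey_group,count,weight",
               "f1,st1,35,400,cop,copepods,5,0.1"), path)
  expect_error(read_stomach_table(path), "stomach_weight")
  writeLines(c(paste("fish_id,station_id,length,body_weight,stomach_weight,",
                     "taxon_name,prey_group,count,weight", sep = ""),
               "f1,st1,35,400,2,cop,copepods,-5,0.1"), path)
  expect_error(read_stomach_table(path), "negative.*row")
  expect_error(read_stomach_table("no/such/file.csv"), "not found")
})

test_that("reader accepts a remapped column dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,st,len,bw,sw,taxon,grp,n,w",
               "f1,st1,35,400,2,cop,copepods,5,0.1",
               "f1,st1,35,400,2,krill,euphausiids,2,0.4",
               "f2,st1,30,250,1.5,cop,copepods,9,0.2"), path)
  recs <- read_stomach_table(path, dialect = list(
    fish_id = "id", station_id = "st", length = "len", body_weight = "bw",
    stomach_weight = "sw", taxon_name = "taxon", prey_group = "grp",
    count = "n", weight = "w"))
  expect_length(recs, 2)
  expect_length(recs[[1]]$items, 2)
})

test_that("diet matrix aggregates per stomach and conserves totals", {
  recs <- structure(list(
    fish("f1", items = list(item("copepods", 10, 2), item("fish", 1, 1))),
    fish("f2", items = list()),
    fish("f3", items = list(item("copepods", 3, 0.5),
                            item("copepods", 4, 0.5, taxon = "cal_fin"),
                            item("parasite", 1, 9))))
  , class = "stomach_records")
  dm <- build_diet_matrix(recs)
  expect_equal(unname(dm$weight["f1", c("copepods", "fish")]), c(2, 1))
  expect_equal(sum(dm$weight["f2", ]), 0)          # zero row retained
  expect_equal(unname(dm$weight["f3", "copepods"]), 1.0)
  # conservation: matrix total equals retained item total (parasite dropped)
  tot_items <- sum(unlist(lapply(recs, function(r)
    vapply(r$items, function(it) if (it$excluded) 0 else it$weight,
           numeric(1)))))
  expect_equal(sum(dm$weight), tot_items, tolerance = 1e-9)
  expect_false(any(c("unidentified", "parasite") %in% colnames(dm$weight)))
})

test_that("diet matrix labelling requires known stations", {
  recs <- structure(list(fish("f1", station = "ghost",
                              items = list(item("copepods", 1, 1)))),
                    class = "stomach_records")
  expect_error(build_diet_matrix(recs, list(station("st1"))), "unknown station")
})

test_that("model filters drop small fish first, then sparse stations", {
  mk_station_fish <- function(st, n, lens) {
    lapply(seq_len(n), function(i)
      fish(sprintf("%s_f%d", st, i), station = st, len = lens[i],
           items = list(item("copepods", 5, 0.5))))
  }
  stomachs <- structure(c(
    mk_station_fish("stA", 10, rep(35, 10)),
    mk_station_fish("stB", 10, c(24, rep(35, 9))),  # loses one fish -> 9 left
    mk_station_fish("stC", 9, rep(35, 9))),         # only 9 stomachs
    class = "stomach_records")
  stations <- list(station("stA"), station("stB"), station("stC"))
  out <- apply_model_filters(stomachs, stations)
  expect_equal(out$report$n_removed_small_fish, 1)
  expect_equal(out$report$n_removed_sparse_stations, 18)  # stB(9) + stC(9)
  expect_equal(out$report$n_retained, 10)
  expect_equal(vapply(out$stations, `[[`, character(1), "station_id"), "stA")
  # idempotence
  out2 <- apply_model_filters(out$stomachs, out$stations)
  expect_equal(out2$report$n_retained, out$report$n_retained)
  expect_equal(out2$report$n_removed_small_fish, 0)
  # unchanged when everything passes
  clean <- structure(mk_station_fish("stA", 10, rep(35, 10)),
                     class = "stomach_records")
  out3 <- apply_model_filters(clean, list(station("stA")))
  expect_equal(out3$report$n_retained, 10)
  # everything removed -> explicit error
  expect_error(apply_model_filters(
    structure(mk_station_fish("stC", 9, rep(35, 9)),
              class = "stomach_records"),
    list(station("stC"))), "no stomachs left")
})
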