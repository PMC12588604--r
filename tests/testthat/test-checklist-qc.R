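# checklist_qc: expertise proxy, effort filters, hex indexing, subsampling.

test_that("expertise counts distinct past species with midrank percentiles", {
  h <- data.frame(observer_id = c("a", "a", "a", "b"),
                  species = c("A", "B", "A", "C"),
                  year = c(2015, 2016, 2018, 2019))
  ex <- compute_expertise(h, observers = c("a", "b", "z"))
  expect_equal(ex[observer_id == "a"]$n_species, 2L)      # {A, B} distinct
  expect_equal(ex[observer_id == "b"]$n_species, 0L)      # 2019 not history
  expect_equal(ex[observer_id == "z"]$n_species, 0L)      # no history kept

  # all-identical counts share one percentile
  same <- compute_expertise(data.frame(
    observer_id = letters[1:5], species = "A", year = 2015))
  expect_equal(unique(same$percentile), 50)

  # 40 observers with counts 1..40: the lowest sits below 2.5
  h40 <- do.call(rbind, lapply(1:40, function(k) data.frame(
    observer_id = sprintf("o%02d", k), species = sprintf("s%02d", 1:k),
    year = 2015)))
  ex40 <- compute_expertise(h40)
  expect_lt(ex40[observer_id == "o01"]$percentile, 2.5)
  expect_gte(ex40[observer_id == "o02"]$percentile, 2.5)
})

make_record <- function(protocol = "Stationary", complete = TRUE,
                        distance = 0, duration = 60, observer = "a",
                        lat = 30, lon = 100) {
  data.frame(checklist_id = "c1", observer_id = observer, protocol = protocol,
             complete_flag = complete, lat = lat, lon = lon, year = 2019,
             doy = 100, start_time = 8, duration_min = duration,
             distance_km = distance, n_observers = 1)
}

test_that("filter applies the published rules with strict bounds", {
  ex <- compute_expertise(data.frame(
    observer_id = rep(letters[1:10], times = 1:10),
    species = unlist(lapply(1:10, seq_len)), year = 2015))
  f <- function(r) filter_checklists(r, ex)

  # paper rules
  rej <- f(make_record("Traveling", distance = 3.5, duration = 60))
  expect_equal(nrow(rej$retained), 0L)
  expect_equal(rej$tally[rule == "distance"]$rejected, 1L)
  rej <- f(make_record(duration = 4))
  expect_equal(rej$tally[rule == "duration"]$rejected, 1L)
  ok <- f(make_record(observer = "e", duration = 60))   # median expertise
  expect_equal(nrow(ok$retained), 1L)

  # strict bounds: exactly 5 and exactly 300 min are rejected
  expect_equal(nrow(f(make_record(duration = 5))$retained), 0L)
  expect_equal(nrow(f(make_record(duration = 300))$retained), 0L)
  expect_equal(nrow(f(make_record(duration = 5.01))$retained), 1L)
  # distance strictly < 3
  expect_equal(nrow(f(make_record("Traveling", distance = 3))$retained), 0L)
  expect_equal(nrow(f(make_record("Traveling", distance = 2.9))$retained), 1L)
  # protocol and completeness
  expect_equal(f(make_record("Other"))$tally[rule == "protocol"]$rejected, 1L)
  expect_equal(f(make_record(complete = FALSE))$tally[
    rule == "incomplete"]$rejected, 1L)
  # malformed records get their own category
  expect_equal(f(make_record(duration = -5))$tally[
    rule == "malformed"]$rejected, 1L)
  expect_equal(f(make_record(lat = 95))$tally[rule == "malformed"]$rejected, 1L)
  # lowest-expertise observer removed (40-observer population: lowest at 1.25)
  ex40 <- compute_expertise(do.call(rbind, lapply(1:40, function(k)
    data.frame(observer_id = sprintf("o%02d", k),
               species = sprintf("s%02d", 1:k), year = 2015))))
  low <- filter_checklists(make_record(observer = "o01"), ex40)
  expect_equal(low$tally[rule == "expertise"]$rejected, 1L)
  expect_equal(nrow(filter_checklists(make_record(observer = "o02"),
                                      ex40)$retained), 1L)
})

test_that("filter retained set is order-independent", {
  w <- test_world()
  ex <- compute_expertise(w$sim$histories,
                          observers = w$sim$observers$observer_id)
  rec <- w$sim$records[1:500]
  a <- filter_checklists(rec, ex)$retained$checklist_id
  b <- filter_checklists(rec[sample.int(500)], ex)$retained$checklist_id
  expect_setequal(a, b)
})

test_that("hex indexing is deterministic, local and hierarchical", {
  expect_identical(hex_index(30.123, 100.456, 7),
                   hex_index(30.123, 100.456, 7))
  # nearby points share a level-7 cell (typical case)
  expect_identical(hex_index(30.1001, 100.2001, 7),
                   hex_index(30.1006, 100.2006, 7))
  # distinct far-apart points get distinct cells
  expect_false(hex_index(30, 100, 7) == hex_index(31, 100, 7))
  # centroid round-trip: a cell's centroid re-indexes to the same cell
  ids <- hex_index(c(10.2, 25.7, 49.9), c(70.3, 99.1, 130.8), 7)
  cen <- hex_centroid(ids)
  expect_identical(hex_index(cen$lat, cen$lon, 7), ids)
  # hierarchy (fallback definition): parent at level 5 equals the level-5
  # index of typical points
  pt <- c(30.12, 100.34)
  expect_identical(hex_parent(hex_index(pt[1], pt[2], 7), 5),
                   hex_index(pt[1], pt[2], 5))
  # level-7 cells are ~5.16 km^2: centroids of distinct adjacent-ish cells
  # are >= ~1 km apart
  expect_gt(gc_distance(cen$lat[1], cen$lon[1],
                        hex_centroid(hex_index(10.25, 70.3, 7))$lat,
                        hex_centroid(hex_index(10.25, 70.3, 7))$lon), 0.5)
  expect_error(hex_index(95, 0, 7), "invalid")
  expect_error(hex_index(10, 190, 7), "invalid")
})

test_that("subsampling keeps one record per key and matches a naive oracle", {
  w <- test_world()
  ex <- compute_expertise(w$sim$histories,
                          observers = w$sim$observers$observer_id)
  keep <- filter_checklists(w$sim$records, ex)$retained
  keyed <- add_spatiotemporal_key(keep[1:800])
  expect_true(all(keyed$hour_bin == floor(keyed$start_time / 2)))

  sub <- subsample_checklists(keyed, seed = 11)
  key <- function(d) paste(d$year, d$doy, d$hour_bin, d$cell_id)
  # oracle: naive group-by on the toy table
  expect_equal(nrow(sub), length(unique(key(keyed))))
  expect_setequal(unique(key(sub)), unique(key(keyed)))
  expect_equal(anyDuplicated(key(sub)), 0L)
  # idempotence
  expect_identical(subsample_checklists(sub, seed = 12)$checklist_id,
                   sub$checklist_id)
  # all-distinct keys: output = input
  distinct <- keyed[!duplicated(key(keyed))]
  expect_setequal(subsample_checklists(distinct, 1)$checklist_id,
                  distinct$checklist_id)
})

test_that("subsampling choice is uniform over a duplicated key", {
  two <- data.frame(checklist_id = c("x", "y"), year = 2019, doy = 1,
                    hour_bin = 0, cell_id = "H7:0:0")
  picks <- vapply(1:2000, function(s)
    subsample_checklists(two, seed = s)$checklist_id, "")
  ph <- mean(picks == "x")
  # binomial 99.9% CI around 0.5 with n = 2000
  expect_true(abs(ph - 0.5) < 3.3 * sqrt(0.25 / 2000))
})
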