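test_that("transfers create lineage-linked children and honour the discard flag", {
  store <- seeded_store()
  parent <- inv_items(store)$item_id[1]

  kids <- transfer_duckweed(store, parent, n_children = 3, discard_parent = TRUE,
                            date = as.Date("2024-01-10"))
  expect_equal(nrow(kids), 3)
  expect_true(all(kids$parent_item_id == parent))
  expect_true(all(kids$sample_id == inv_items(store)$sample_id[1]))
  expect_equal(inv_items(store)$status[1], "discarded")
  expect_false(parent %in% active_inventory(store)$item_id)

  # a discarded parent cannot be transferred again
  expect_error(transfer_duckweed(store, parent, 1), class = "frondkit_lineage_error")

  # keep-parent variant
  k2 <- transfer_duckweed(store, kids$item_id[1], n_children = 1,
                          discard_parent = FALSE, date = as.Date("2024-01-12"))
  expect_equal(nrow(k2), 1)
  expect_equal(filter(inv_items(store), item_id == kids$item_id[1])$status, "active")
})

test_that("a chain of 5 transfers yields 5 ordered ancestors and no cycle", {
  store <- seeded_store()
  cur <- inv_items(store)$item_id[1]
  chain <- cur
  for (i in 1:5) {
    cur <- transfer_duckweed(store, cur, 1, date = as.Date("2024-01-01") + i)$item_id
    chain <- c(chain, cur)
  }
  anc <- inv_lineage(store, cur)
  expect_equal(anc$item_id, rev(chain[-length(chain)]))
  expect_equal(nrow(anc), 5)
})

test_that("contamination logging discards the item and stays queryable by month", {
  store <- seeded_store()
  s <- store$samples$sample_id[1]
  img <- touch_image()
  ids <- purrr::map_int(1:4, ~ inv_add_item(store, s)$item_id)

  times <- as.POSIXct(c("2024-03-02 10:00:00", "2024-03-20 11:00:00",
                        "2024-03-28 09:00:00", "2024-04-05 16:00:00"), tz = "UTC")
  n_active_before <- nrow(active_inventory(store))
  for (i in 1:4) log_contamination(store, ids[i], img, notes = paste("event", i),
                                   timestamp = times[i])
  expect_equal(nrow(active_inventory(store)), n_active_before - 4)

  counts <- contamination_by_month(store)
  expect_equal(counts, tibble::tibble(month = c("2024-03", "2024-04"), n = c(3L, 1L)))

  # two associations per event, retrievable
  a <- inv_associations(store, ids[1])
  expect_setequal(a$key, c("contamination_image", "contamination_notes"))

  # already-discarded item cannot be logged again; missing file is an input error
  expect_error(log_contamination(store, ids[1], img), class = "frondkit_lineage_error")
  it <- inv_add_item(store, s)
  expect_error(log_contamination(store, it$item_id, "no-such-file.jpg"),
               class = "frondkit_input_error")
})

test_that("plate treatments round-trip, conflict on redefinition, and bulk-join", {
  store <- seeded_store()
  s <- store$samples$sample_id[1]
  plan <- inv_new_plan(store)$plan_id
  ids <- purrr::map_int(1:15, ~ inv_add_item(store, s)$item_id)
  inv_add_operation(store, plan, "image_plate", inputs = ids)

  doses <- rep(c(0, 50, 100, 150, 300), each = 3)
  reps <- rep(1:3, 5)
  for (i in 1:15) {
    define_plate_treatment(store, plan, ids[i],
                           list(NaCl_mM = doses[i], replicate = reps[i]))
  }
  tr <- plan_treatments(store, plan)
  expect_equal(nrow(tr), 15)
  expect_equal(tr$NaCl_mM[match(ids, tr$item_id)], doses)
  expect_equal(tr$replicate[match(ids, tr$item_id)], reps)

  expect_error(define_plate_treatment(store, plan, ids[1], list(NaCl_mM = 999)),
               class = "frondkit_conflict_error")

  # an item not referenced by the plan cannot carry a treatment
  outsider <- inv_add_item(store, s)$item_id
  expect_error(define_plate_treatment(store, plan, outsider, list(NaCl_mM = 0)),
               class = "frondkit_input_error")
})

test_that("query_plan_images joins images to treatments, sorted, pure", {
  store <- seeded_store()
  s <- store$samples$sample_id[1]
  plan <- inv_new_plan(store)$plan_id
  img <- touch_image()
  ids <- purrr::map_int(1:15, ~ inv_add_item(store, s)$item_id)
  inv_add_operation(store, plan, "growth_assay", inputs = ids)
  for (i in 1:15) {
    define_plate_treatment(store, plan, ids[i],
                           list(NaCl_mM = rep(c(0, 50, 100, 150, 300), 3)[i]))
  }
  dates <- as.Date("2024-05-01") + seq(0, 10, 2)
  # insert out of order on purpose
  for (d in rev(seq_along(dates))) {
    for (i in sample(15)) {
      inv_associate(store, ids[i], "image", img, is_file = TRUE,
                    timestamp = as.POSIXct(dates[d], tz = "UTC") + i)
    }
  }
  rows <- query_plan_images(store, plan)
  expect_gte(nrow(rows), 90)
  expect_true(all(rows$item_id %in% ids))
  expect_true("NaCl_mM" %in% names(rows))
  expect_equal(rows, arrange(rows, item_id, date))     # sorted
  expect_identical(rows, query_plan_images(store, plan))  # pure

  expect_error(query_plan_images(store, 999), class = "frondkit_not_found")
  empty_plan <- inv_new_plan(store)$plan_id
  expect_equal(nrow(query_plan_images(store, empty_plan)), 0)
})

test_that("a store survives a save/load round trip unchanged", {
  store <- seeded_store()
  s <- store$samples$sample_id[1]
  plan <- inv_new_plan(store)$plan_id
  img <- touch_image()
  kids <- transfer_duckweed(store, inv_items(store)$item_id[1], 2,
                            date = as.Date("2024-02-01"))
  inv_add_operation(store, plan, "growth_assay", inputs = kids$item_id,
                    params = list(media = "SH4"), technician = "tech-a")
  define_plate_treatment(store, plan, kids$item_id[1], list(NaCl_mM = 50, replicate = 1))
  define_plate_treatment(store, plan, kids$item_id[2], list(NaCl_mM = 100, replicate = 1))
  inv_associate(store, kids$item_id[1], "image", img, is_file = TRUE,
                timestamp = as.POSIXct("2024-02-03 10:00:00", tz = "UTC"))
  log_contamination(store, kids$item_id[2], img,
                    timestamp = as.POSIXct("2024-02-04 09:00:00", tz = "UTC"))

  path <- file.path(withr::local_tempdir(), "store.json")
  inv_save(store, path)
  re <- inv_load(path)
  expect_equal(re$samples, store$samples)
  expect_equal(re$items, store$items)
  expect_equal(re$associations, store$associations)
  expect_equal(re$plans, store$plans)
  expect_equal(re$operations, store$operations)
  expect_equal(re$next_item_id, store$next_item_id)

  # ids keep advancing from where the loaded store left off
  expect_equal(inv_add_item(re, s)$item_id, store$next_item_id)
})

test_that("active-inventory size changes by the exact amount per operation", {
  store <- seeded_store()
  img <- touch_image()
  set.seed(42)
  for (i in 1:30) {
    act <- active_inventory(store)
    n0 <- nrow(act)
    if (runif(1) < 0.7 || n0 < 2) {
      parent <- sample(act$item_id, 1)
      n_kids <- sample(1:3, 1)
      discard <- runif(1) < 0.5
      transfer_duckweed(store, parent, n_kids, discard_parent = discard,
                        date = as.Date("2024-03-01") + i)
      expect_equal(nrow(active_inventory(store)), n0 + n_kids - as.integer(discard))
    } else {
      log_contamination(store, sample(act$item_id, 1), img,
                        timestamp = as.POSIXct("2024-03-01", tz = "UTC") + i)
      expect_equal(nrow(active_inventory(store)), n0 - 1)
    }
  }
  # lineage stays acyclic from every leaf
  for (id in inv_items(store)$item_id) expect_no_error(inv_lineage(store, id))
})
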