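#' A desk-scale duckweed inventory store
#'
#' An in-memory (environment-backed) strongly-typed inventory mirroring the
#' LIMS data model image-analysis workflows lean on: samples (genotypes),
#' uniquely identified items with lineage and status, append-only key-value
#' data associations (optionally file-valued), and plans holding operations
#' with typed inputs/outputs. IDs are assigned sequentially by the store and
#' never reused. Persist with [inv_save()] / [inv_load()] (a single
#' human-readable JSON document).
#'
#' @return An empty store of class `duckweed_store`.
#' @export
inv_store <- function() {
  e <- new.env(parent = emptyenv())
  e$samples <- tibble(sample_id = integer(), name = character(),
                      sample_type = character())
  e$items <- tibble(item_id = integer(), sample_id = integer(),
                    container_type = character(), location = character(),
                    status = character(), parent_item_id = integer(),
                    created = as.Date(character()))
  e$associations <- tibble(item_id = integer(), key = character(),
                           value = character(), is_file = logical(),
                           timestamp = as.POSIXct(character(), tz = "UTC"))
  e$plans <- tibble(plan_id = integer())
  e$operations <- tibble(plan_id = integer(), op_index = integer(),
                         op_name = character(), inputs = list(),
                         outputs = list(), params = list(),
                         executed = as.POSIXct(character(), tz = "UTC"),
                         technician = character())
  e$next_sample_id <- 1L; e$next_item_id <- 1L; e$next_plan_id <- 1L
  class(e) <- "duckweed_store"
  e
}

#' @export
print.duckweed_store <- function(x, ...) {
  cat(sprintf(paste0("<duckweed_store> %d samples, %d items (%d active), ",
                     "%d associations, %d plans\n"),
              nrow(x$samples), nrow(x$items),
              sum(x$items$status == "active"), nrow(x$associations),
              nrow(x$plans)))
  invisible(x)
}

# normalise a JSON-simplified column back into a plain list of length n
json_list_col <- function(x, n) {
  if (is.null(x)) return(rep(list(NULL), n))
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE])))
  }
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  if (is.list(x)) return(x)
  as.list(x)
}

floor_time <- function(t) {
  as.POSIXct(floor(as.numeric(as.POSIXct(t))), origin = "1970-01-01", tz = "UTC")
}

item_row <- function(store, item_id) {
  i <- which(store$items$item_id == item_id)
  if (length(i) != 1) {
    stop_frondkit(paste0("unknown item #", item_id), "frondkit_lineage_error")
  }
  i
}

#' Register a sample (e.g. a duckweed genotype)
#'
#' @param store a [inv_store()].
#' @param name non-empty sample name.
#' @param sample_type free-text type tag.
#' @return One-row tibble with the assigned `sample_id`.
#' @export
inv_add_sample <- function(store, name, sample_type = "duckweed genotype") {
  if (!nzchar(name)) stop_frondkit("sample name must be non-empty",
                                   "frondkit_input_error")
  row <- tibble(sample_id = store$next_sample_id, name = name,
                sample_type = sample_type)
  store$samples <- bind_rows(store$samples, row)
  store$next_sample_id <- store$next_sample_id + 1L
  row
}

#' Add an inventory item
#'
#' @param store a [inv_store()].
#' @param sample_id sample the item manifests.
#' @param container_type item container type.
#' @param location free-text location.
#' @param parent_item_id optional parent item (lineage link).
#' @param created creation date; must not precede the parent's.
#' @return One-row tibble with the assigned `item_id`.
#' @export
inv_add_item <- function(store, sample_id,
                         container_type = "Container of Duckweed",
                         location = "bench", parent_item_id = NA_integer_,
                         created = Sys.Date()) {
  if (!sample_id %in% store$samples$sample_id) {
    stop_frondkit(paste0("unknown sample #", sample_id), "frondkit_input_error")
  }
  created <- as.Date(created)
  if (!is.na(parent_item_id)) {
    p <- item_row(store, parent_item_id)
    if (created < store$items$created[p]) {
      stop_frondkit("child created before its parent", "frondkit_lineage_error")
    }
  }
  row <- tibble(item_id = store$next_item_id, sample_id = as.integer(sample_id),
                container_type = container_type, location = location,
                status = "active", parent_item_id = as.integer(parent_item_id),
                created = created)
  store$items <- bind_rows(store$items, row)
  store$next_item_id <- store$next_item_id + 1L
  row
}

#' List items; active inventory
#'
#' `inv_items()` returns all items; `active_inventory()` only the active
#' ones (discarded items never appear there).
#'
#' @param store a [inv_store()].
#' @return A tibble of item records.
#' @export
inv_items <- function(store) store$items

#' @rdname inv_items
#' @export
active_inventory <- function(store) filter(store$items, .data$status == "active")

#' Transfer duckweed from a parent container to new ones
#'
#' Creates `n_children` fresh active items with the parent's sample and a
#' lineage link to it; the parent is discarded iff `discard_parent`.
#'
#' @param store a [inv_store()].
#' @param parent_item_id the (active) parent item.
#' @param n_children number of daughter containers (>= 1).
#' @param discard_parent discard the parent after the transfer? Default
#'   `FALSE` (the source culture is kept).
#' @param date transfer date.
#' @param location location for the children.
#' @return Tibble of the new child item records.
#' @export
transfer_duckweed <- function(store, parent_item_id, n_children = 1,
                              discard_parent = FALSE, date = Sys.Date(),
                              location = NULL) {
  if (!is_count(n_children) || n_children < 1) {
    stop_frondkit("`n_children` must be >= 1", "frondkit_input_error")
  }
  p <- item_row(store, parent_item_id)
  if (store$items$status[p] != "active") {
    stop_frondkit(paste0("parent item #", parent_item_id, " is discarded"),
                  "frondkit_lineage_error")
  }
  parent <- store$items[p, ]
  children <- map(seq_len(n_children), function(i) {
    inv_add_item(store, sample_id = parent$sample_id,
                 container_type = parent$container_type,
                 location = location %||% parent$location,
                 parent_item_id = parent$item_id, created = as.Date(date))
  }) |> list_rbind()
  if (discard_parent) {
    store$items$status[item_row(store, parent_item_id)] <- "discarded"
  }
  children
}

#' Walk an item's lineage
#'
#' @param store a [inv_store()].
#' @param item_id the item to start from.
#' @return Tibble of ancestor item records, nearest first.
#' @export
inv_lineage <- function(store, item_id) {
  out <- list(); cur <- item_id; seen <- integer()
  repeat {
    i <- item_row(store, cur)
    pid <- store$items$parent_item_id[i]
    if (is.na(pid)) break
    if (pid %in% seen) {
      stop_frondkit("cycle detected in lineage", "frondkit_lineage_error")
    }
    seen <- c(seen, pid)
    out[[length(out) + 1]] <- store$items[item_row(store, pid), ]
    cur <- pid
  }
  if (length(out)) list_rbind(out) else store$items[0, ]
}

#' Attach a key-value or file data association to an item
#'
#' Associations are append-only history: several may share a key; the
#' `(item_id, key, timestamp)` triple must be unique (second granularity).
#'
#' @param store a [inv_store()].
#' @param item_id target item.
#' @param key association key.
#' @param value text/number, or a file path when `is_file`.
#' @param is_file is `value` a file path? The file must exist at write time.
#' @param timestamp association time (defaults to now).
#' @return The one-row association tibble.
#' @export
inv_associate <- function(store, item_id, key, value, is_file = FALSE,
                          timestamp = Sys.time()) {
  item_row(store, item_id)
  if (is_file && !file.exists(as.character(value))) {
    stop_frondkit(paste0("file does not exist: ", value), "frondkit_input_error")
  }
  ts <- floor_time(timestamp)
  dup <- store$associations$item_id == item_id &
    store$associations$key == key & store$associations$timestamp == ts
  if (any(dup)) {
    stop_frondkit("duplicate (item, key, timestamp) association",
                  "frondkit_conflict_error")
  }
  row <- tibble(item_id = as.integer(item_id), key = key,
                value = as.character(value), is_file = is_file, timestamp = ts)
  store$associations <- bind_rows(store$associations, row)
  row
}

#' Retrieve data associations for an item
#'
#' @param store a [inv_store()].
#' @param item_id target item.
#' @param key optional key filter.
#' @param latest if `TRUE`, return only the most recent value per key
#'   (latest-wins at query time; the history itself is append-only).
#' @return A tibble of associations.
#' @export
inv_associations <- function(store, item_id, key = NULL, latest = FALSE) {
  a <- filter(store$associations, .data$item_id == !!item_id)
  if (!is.null(key)) a <- filter(a, .data$key == !!key)
  if (latest) {
    a <- a |> group_by(.data$key) |>
      slice_max(.data$timestamp, n = 1, with_ties = FALSE) |> ungroup()
  }
  arrange(a, .data$key, .data$timestamp)
}

#' Log a contamination event
#'
#' Records the evidence photo and notes as data associations
#' (`contamination_image`, `contamination_notes`) and discards the item, so
#' contamination rates over time remain queryable
#' ([contamination_by_month()]).
#'
#' @param store a [inv_store()].
#' @param item_id the contaminated (active) item.
#' @param image_path photo of the contamination; must exist.
#' @param notes free-text notes.
#' @param timestamp event time.
#' @return The updated item record, invisibly.
#' @export
log_contamination <- function(store, item_id, image_path, notes = "",
                              timestamp = Sys.time()) {
  i <- item_row(store, item_id)
  if (store$items$status[i] != "active") {
    stop_frondkit(paste0("item #", item_id, " is already discarded"),
                  "frondkit_lineage_error")
  }
  if (!file.exists(image_path)) {
    stop_frondkit(paste0("contamination image not found: ", image_path),
                  "frondkit_input_error")
  }
  inv_associate(store, item_id, "contamination_image", image_path,
                is_file = TRUE, timestamp = timestamp)
  inv_associate(store, item_id, "contamination_notes", notes,
                timestamp = timestamp)
  store$items$status[i] <- "discarded"
  invisible(store$items[i, ])
}

#' Contamination counts per calendar month
#'
#' @param store a [inv_store()].
#' @return Tibble `month` (`"YYYY-MM"`), `n`.
#' @export
contamination_by_month <- function(store) {
  store$associations |>
    filter(.data$key == "contamination_image") |>
    mutate(month = format(.data$timestamp, "%Y-%m")) |>
    count(.data$month)
}

#' Create a plan and add operations to it
#'
#' A plan is a connected series of operations (an experiment); operations
#' carry a name, input/output item references, a parameter map, an
#' execution time and the technician.
#'
#' @param store a [inv_store()].
#' @return `inv_new_plan()`: one-row tibble with the new `plan_id`.
#' @export
inv_new_plan <- function(store) {
  row <- tibble(plan_id = store$next_plan_id)
  store$plans <- bind_rows(store$plans, row)
  store$next_plan_id <- store$next_plan_id + 1L
  row
}

assert_plan <- function(store, plan_id) {
  if (!plan_id %in% store$plans$plan_id) {
    stop_frondkit(paste0("unknown plan #", plan_id), "frondkit_not_found")
  }
}

#' @rdname inv_new_plan
#' @param plan_id plan to extend.
#' @param op_name operation type name.
#' @param inputs,outputs integer vectors of item ids (must exist).
#' @param params named list of operation parameters.
#' @param executed execution time.
#' @param technician who ran it.
#' @return `inv_add_operation()`: the one-row operation tibble.
#' @export
inv_add_operation <- function(store, plan_id, op_name, inputs = integer(),
                              outputs = integer(), params = list(),
                              executed = Sys.time(), technician = NA_character_) {
  assert_plan(store, plan_id)
  for (id in c(inputs, outputs)) item_row(store, id)
  row <- tibble(plan_id = as.integer(plan_id),
                op_index = sum(store$operations$plan_id == plan_id) + 1L,
                op_name = op_name, inputs = list(as.integer(inputs)),
                outputs = list(as.integer(outputs)), params = list(params),
                executed = floor_time(executed), technician = technician)
  store$operations <- bind_rows(store$operations, row)
  row
}

plan_item_ids <- function(store, plan_id) {
  ops <- filter(store$operations, .data$plan_id == !!plan_id)
  sort(unique(c(unlist(ops$inputs), unlist(ops$outputs))))
}

#' Record a plate's treatment metadata within a plan
#'
#' Adds a `define_plate_treatment` operation holding the treatment
#' key-value map for one item. At most one such definition per item per
#' plan; the item must already be referenced by the plan.
#'
#' @param store a [inv_store()].
#' @param plan_id the experiment plan.
#' @param item_id the plate item (must appear in the plan's operations).
#' @param treatment named list, e.g. `list(NaCl_mM = 150, replicate = 2)`.
#' @return The operation row, invisibly.
#' @export
define_plate_treatment <- function(store, plan_id, item_id, treatment) {
  assert_plan(store, plan_id)
  item_row(store, item_id)
  if (!item_id %in% plan_item_ids(store, plan_id)) {
    stop_frondkit(paste0("item #", item_id, " is not part of plan #", plan_id),
                  "frondkit_input_error")
  }
  ops <- filter(store$operations, .data$plan_id == !!plan_id,
                .data$op_name == "define_plate_treatment")
  if (any(map_lgl(ops$outputs, ~ item_id %in% .x))) {
    stop_frondkit(paste0("treatment already defined for item #", item_id,
                         " in plan #", plan_id), "frondkit_conflict_error")
  }
  invisible(inv_add_operation(store, plan_id, "define_plate_treatment",
                              outputs = item_id, params = treatment))
}

#' Treatments defined in a plan
#'
#' @param store a [inv_store()].
#' @param plan_id the plan.
#' @return A wide tibble: `item_id` plus one column per treatment key.
#' @export
plan_treatments <- function(store, plan_id) {
  assert_plan(store, plan_id)
  ops <- filter(store$operations, .data$plan_id == !!plan_id,
                .data$op_name == "define_plate_treatment")
  if (nrow(ops) == 0) return(tibble(item_id = integer()))
  map2(ops$outputs, ops$params,
       ~ as_tibble(c(list(item_id = .x[1]), .y))) |>
    list_rbind() |>
    arrange(.data$item_id)
}

#' Pull every plate image of an experiment, joined to its treatment
#'
#' One row per `image` file association on items of container type
#' `"Container of Duckweed"` referenced in the plan, joined to the plan's
#' treatment metadata and sorted by `(item_id, date)`. This is the scripted
#' retrieval pattern image-analysis notebooks start from.
#'
#' @param store a [inv_store()].
#' @param plan_id the experiment plan.
#' @return A tibble: `item_id`, `date`, `image_path`, treatment columns.
#' @export
query_plan_images <- function(store, plan_id) {
  assert_plan(store, plan_id)
  ids <- plan_item_ids(store, plan_id)
  dishes <- filter(store$items, .data$item_id %in% ids,
                   .data$container_type == "Container of Duckweed")
  imgs <- store$associations |>
    filter(.data$item_id %in% dishes$item_id, .data$key == "image",
           .data$is_file) |>
    transmute(item_id = .data$item_id, date = as.Date(.data$timestamp),
              image_path = .data$value)
  tr <- plan_treatments(store, plan_id)
  if (nrow(tr) > 0) imgs <- left_join(imgs, tr, by = "item_id")
  arrange(imgs, .data$item_id, .data$date)
}

#' Persist / reload a store
#'
#' The store serialises to a single human-readable JSON document; attached
#' images stay on disk and are referenced by path.
#'
#' @param store a [inv_store()].
#' @param path JSON file path.
#' @return `inv_save()`: `path` invisibly. `inv_load()`: the restored store.
#' @export
inv_save <- function(store, path) {
  doc <- list(
    samples = store$samples,
    items = mutate(store$items, created = format(.data$created)),
    associations = mutate(store$associations,
                          timestamp = format(.data$timestamp,
                                             "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    plans = store$plans,
    operations = mutate(store$operations,
                        executed = format(.data$executed,
                                          "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    counters = list(sample = store$next_sample_id, item = store$next_item_id,
                    plan = store$next_plan_id)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname inv_save
#' @export
inv_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  store <- inv_store()
  if (length(doc$samples)) store$samples <- as_tibble(doc$samples)
  if (length(doc$items)) {
    store$items <- as_tibble(doc$items) |>
      mutate(created = as.Date(.data$created),
             parent_item_id = as.integer(.data$parent_item_id),
             item_id = as.integer(.data$item_id),
             sample_id = as.integer(.data$sample_id))
  }
  if (length(doc$associations)) {
    store$associations <- as_tibble(doc$associations) |>
      mutate(item_id = as.integer(.data$item_id),
             timestamp = as.POSIXct(.data$timestamp,
                                    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  }
  if (length(doc$plans)) {
    store$plans <- tibble(plan_id = as.integer(doc$plans$plan_id))
  }
  if (length(doc$operations)) {
    # re-read operations unsimplified so per-row params keep exactly their
    # own keys (vector simplification would merge keys across rows)
    ops <- jsonlite::read_json(path, simplifyVector = FALSE)$operations
    store$operations <- tibble(
      plan_id = map_int(ops, ~ as.integer(.x$plan_id)),
      op_index = map_int(ops, ~ as.integer(.x$op_index)),
      op_name = map_chr(ops, "op_name"),
      inputs = map(ops, ~ as.integer(unlist(.x$inputs))),
      outputs = map(ops, ~ as.integer(unlist(.x$outputs))),
      params = map(ops, ~ lapply(.x$params, function(v) {
        if (is.list(v)) unlist(v) else v
      })),
      executed = as.POSIXct(map_chr(ops, "executed"),
                            format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      technician = map_chr(ops, ~ .x$technician %||% NA_character_)
    )
  }
  store$next_sample_id <- as.integer(doc$counters$sample)
  store$next_item_id <- as.integer(doc$counters$item)
  store$next_plan_id <- as.integer(doc$counters$plan)
  store
}
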