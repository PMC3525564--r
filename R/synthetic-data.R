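#' Define a complete synthetic clone-culture scenario
#'
#' A `clone_scenario` bundles everything needed to generate a synthetic
#' single-cell genotyping experiment with known ground truth: a segregation
#' model (molecule-level drift or faithful segregation units), the founder
#' state, the passaging protocol, optional metastable reorganization events
#' with a nuclear-hitchhiking growth advantage, and the Padlock/RCA detection
#' model applied to every recorded cell.
#'
#' @param model `"molecule_drift"` (individual molecules segregate; see
#'   [simulate_drift()]) or `"unit_faithful"` (multi-copy units replicate
#'   faithfully and segregate; see [unit_cell()]).
#' @param founder_load Founder heteroplasmy in `[0, 1]`.
#' @param copy_number Total mtDNA copies per cell N. For `unit_faithful`,
#'   `units_per_cell * unit_size` must equal `copy_number`.
#' @param units_per_cell,unit_size Unit organisation (required for
#'   `unit_faithful`; ignored otherwise).
#' @param n_passages Number of passages after the first outgrowth.
#' @param population_cap Cells at confluence (default 10,000; scaled down
#'   from the ~10^6 cells of a confluent dish, see vignette).
#' @param bottleneck_fraction Split fraction (default 0.1).
#' @param replication_mode,turnover_events_per_cycle Molecule-model options,
#'   passed to [drift_config()].
#' @param reorganization_rate Probability per cell division that the dividing
#'   cell undergoes a metastable reorganization (default 0: faithful
#'   replication only).
#' @param reorganization_kind `"single_unit"` (one unit's composition is
#'   redrawn from the cell's current load) or `"full_redistribution"` (all
#'   molecules redistributed into fresh units, [redistribute_all()]).
#' @param advantage_multiplier Relative division propensity granted to a
#'   reorganized lineage (>= 1; default 1 = neutral). This models a growth
#'   advantage arising from the unstable host nucleus, on which an altered
#'   segregation unit "hitchhikes" - not a fitness effect of the mtDNA
#'   genotype itself.
#' @param forced_event_passage Optional passage index at which exactly one
#'   reorganization event is forced on one random cell before regrowth,
#'   regardless of `reorganization_rate` (useful for controlled experiments).
#' @param detection A [detection_config()]. Default: independent-molecule
#'   detection at 3.3% efficiency for `molecule_drift` (about 60 dots/cell at
#'   1,800 copies), unit-clustered detection at 5% for `unit_faithful`.
#' @param seed Optional integer seed; [generate_scenario()] is deterministic
#'   given the scenario and seed.
#'
#' @return An object of class `clone_scenario`.
#' @examples
#' clone_scenario("unit_faithful", founder_load = 0.5, copy_number = 72,
#'                units_per_cell = 9, unit_size = 8, n_passages = 3,
#'                population_cap = 500, seed = 1)
#' @export
clone_scenario <- function(model = c("molecule_drift", "unit_faithful"),
                           founder_load,
                           copy_number,
                           units_per_cell = NULL,
                           unit_size = NULL,
                           n_passages,
                           population_cap = 10000,
                           bottleneck_fraction = 0.1,
                           replication_mode = c("relaxed_urn", "strict_doubling"),
                           turnover_events_per_cycle = 0,
                           reorganization_rate = 0,
                           reorganization_kind = c("single_unit", "full_redistribution"),
                           advantage_multiplier = 1,
                           forced_event_passage = NULL,
                           detection = NULL,
                           seed = NULL) {
  model <- match.arg(model)
  replication_mode <- match.arg(replication_mode)
  reorganization_kind <- match.arg(reorganization_kind)
  founder_load <- check_fraction(founder_load, "founder_load")
  copy_number <- check_count(copy_number, "copy_number", min = 1L)
  n_passages <- check_count(n_passages, "n_passages")
  population_cap <- check_count(population_cap, "population_cap", min = 1L)
  if (model == "unit_faithful") {
    units_per_cell <- check_count(units_per_cell, "units_per_cell", min = 1L)
    unit_size <- check_count(unit_size, "unit_size", min = 1L)
    if (units_per_cell * unit_size != copy_number) {
      stop("infeasible scenario: units_per_cell * unit_size must equal copy_number",
           call. = FALSE)
    }
  }
  if (!is.numeric(reorganization_rate) || reorganization_rate < 0 ||
      reorganization_rate > 1) {
    stop("reorganization_rate must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(advantage_multiplier) || advantage_multiplier < 1) {
    stop("advantage_multiplier must be >= 1", call. = FALSE)
  }
  if (!is.null(forced_event_passage)) {
    forced_event_passage <- check_count(forced_event_passage, "forced_event_passage",
                                        min = 1L)
    if (forced_event_passage > n_passages) {
      stop("forced_event_passage exceeds n_passages", call. = FALSE)
    }
  }
  if (is.null(detection)) {
    detection <- if (model == "molecule_drift") {
      detection_config(0.0333, "independent_molecules")
    } else {
      detection_config(0.05, "unit_clustered")
    }
  }
  stopifnot(inherits(detection, "detection_config"))
  if (model == "molecule_drift" && detection$mode == "unit_clustered") {
    stop("unit_clustered detection requires the unit_faithful model", call. = FALSE)
  }
  structure(
    list(
      model = model,
      founder_load = founder_load,
      copy_number = copy_number,
      units_per_cell = units_per_cell,
      unit_size = unit_size,
      n_passages = n_passages,
      population_cap = population_cap,
      bottleneck_fraction = bottleneck_fraction,
      replication_mode = replication_mode,
      turnover_events_per_cycle = turnover_events_per_cycle,
      reorganization_rate = reorganization_rate,
      reorganization_kind = reorganization_kind,
      advantage_multiplier = advantage_multiplier,
      forced_event_passage = forced_event_passage,
      detection = detection,
      seed = seed
    ),
    class = "clone_scenario"
  )
}

#' @export
print.clone_scenario <- function(x, ...) {
  cat(sprintf("<clone_scenario> %s: founder %.3f, N = %d%s, %d passages, cap %d\n",
              x$model, x$founder_load, x$copy_number,
              if (x$model == "unit_faithful")
                sprintf(" (%d units x %d)", x$units_per_cell, x$unit_size) else "",
              x$n_passages, x$population_cap))
  print(x$detection)
  invisible(x)
}

#' Preset scenarios mirroring the study's cybrid clones
#'
#' Named [clone_scenario()] presets for the experimental systems the
#' simulators are calibrated against:
#' \describe{
#'   \item{`V_3.2`}{Stably heteroplasmic clone: founder load 67%, ~1,800
#'     copies/cell, 81 passages, molecule-level drift.}
#'   \item{`G_55.2`}{Low-copy clone: founder load 55%, ~350 copies/cell, 32
#'     passages, molecule-level drift with mtDNA turnover enabled (2
#'     degradation/replication events per molecule per cycle).}
#'   \item{`unit_toy`}{The schematic 72-molecule cell: 9 segregation units of
#'     8 copies, 4 mutant each (50% load), faithful unit segregation.}
#'   \item{`V_50_like`}{A near-homoplasmic mutant clone (95% load, 100 units
#'     of 20 copies) with rare reorganization events and a two-fold growth
#'     advantage for reorganized lineages, emulating the discrete
#'     heteroplasmy sweeps seen in shifting clones.}
#' }
#'
#' @param population_cap Confluence cap applied to every preset (default
#'   10,000).
#' @param seed Seed stored in every preset (default 1).
#' @return A named list of `clone_scenario` objects.
#' @examples
#' names(clone_presets())
#' clone_presets()$V_3.2$founder_load
#' @export
clone_presets <- function(population_cap = 10000, seed = 1) {
  list(
    V_3.2 = clone_scenario(
      "molecule_drift", founder_load = 0.67, copy_number = 1800,
      n_passages = 81, population_cap = population_cap,
      detection = detection_config(0.0333, "independent_molecules"),
      seed = seed
    ),
    G_55.2 = clone_scenario(
      "molecule_drift", founder_load = 0.55, copy_number = 350,
      n_passages = 32, population_cap = population_cap,
      turnover_events_per_cycle = 2,
      detection = detection_config(0.15, "independent_molecules"),
      seed = seed
    ),
    unit_toy = clone_scenario(
      "unit_faithful", founder_load = 0.5, copy_number = 72,
      units_per_cell = 9, unit_size = 8, n_passages = 5,
      population_cap = population_cap,
      detection = detection_config(0.05, "unit_clustered"),
      seed = seed
    ),
    V_50_like = clone_scenario(
      "unit_faithful", founder_load = 0.95, copy_number = 2000,
      units_per_cell = 100, unit_size = 20, n_passages = 20,
      population_cap = population_cap,
      reorganization_rate = 5e-4, reorganization_kind = "single_unit",
      advantage_multiplier = 2,
      detection = detection_config(0.05, "unit_clustered"),
      seed = seed
    )
  )
}

#' Generate a synthetic single-cell genotyping experiment
#'
#' Runs the scenario's segregation model through the passaging protocol,
#' applies the Padlock/RCA detection model to every cell of every recorded
#' passage, and returns the per-cell dot counts together with the full ground
#' truth (true loads, reorganization events, advantaged lineages). The result
#' is deterministic given the scenario and its seed.
#'
#' @param scenario A [clone_scenario()].
#' @return An object of class `synthetic_dataset`: a list with
#'   \describe{
#'     \item{`cells`}{Data frame: `passage`, `cell_id`, `true_load`,
#'       `red_dots`, `green_dots`, `yellow_dots`, `advantaged`.}
#'     \item{`events`}{Data frame of reorganization events: `passage`,
#'       `kind`, `unit_size`, `old_mutant_copies`, `new_mutant_copies`,
#'       `advantaged`.}
#'     \item{`scenario`}{The scenario echo.}
#'   }
#' @examples
#' sc <- clone_scenario("molecule_drift", founder_load = 1, copy_number = 50,
#'                      n_passages = 2, population_cap = 200, seed = 1)
#' ds <- generate_scenario(sc)
#' all(ds$cells$true_load == 1)
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "clone_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  if (scenario$model == "molecule_drift") {
    generate_molecule_scenario(scenario)
  } else {
    generate_unit_scenario(scenario)
  }
}

generate_molecule_scenario <- function(scenario) {
  cfg <- drift_config(
    founder_heteroplasmy = scenario$founder_load,
    copy_number = scenario$copy_number,
    n_passages = scenario$n_passages,
    population_cap = scenario$population_cap,
    bottleneck_fraction = scenario$bottleneck_fraction,
    replication_mode = scenario$replication_mode,
    turnover_events_per_cycle = scenario$turnover_events_per_cycle
  )
  sim <- simulate_drift(cfg)
  tabs <- lapply(sim$snapshots, function(s) {
    ro <- readout_independent(s$mutant, s$copy_numbers - s$mutant,
                              scenario$detection)
    data.frame(
      passage = s$passage_index,
      cell_id = seq_along(s$heteroplasmies),
      true_load = s$heteroplasmies,
      ro,
      advantaged = FALSE
    )
  })
  structure(
    list(cells = do.call(rbind, tabs), events = empty_event_log(),
         scenario = scenario),
    class = "synthetic_dataset"
  )
}

empty_event_log <- function() {
  data.frame(
    passage = integer(0), kind = character(0), unit_size = integer(0),
    old_mutant_copies = integer(0), new_mutant_copies = integer(0),
    advantaged = logical(0)
  )
}

generate_unit_scenario <- function(scenario) {
  U <- scenario$units_per_cell
  n <- scenario$unit_size
  cap <- scenario$population_cap
  k0 <- as.integer(round_half_up(scenario$founder_load * n))
  # mutable state shared by the event helpers
  k_reg <- k0                               # genotype registry (mutant copies)
  counts <- matrix(0L, nrow = cap, ncol = 1L)
  counts[1L, 1L] <- U
  prop <- rep(1, cap)
  size <- 1L
  events <- list()
  geno_index <- function(k_val) {
    hit <- match(k_val, k_reg)
    if (is.na(hit)) {
      k_reg <<- c(k_reg, k_val)
      counts <<- cbind(counts, 0L)
      hit <- length(k_reg)
    }
    hit
  }
  reorganize_cell <- function(i, passage) {
    row <- counts[i, ]
    u_i <- sum(row)
    load_i <- sum(row * k_reg) / (u_i * n)
    advantaged <- scenario$advantage_multiplier > 1
    if (scenario$reorganization_kind == "single_unit") {
      g <- sample.int(length(row), 1L, prob = row)
      new_k <- rbinom(1L, n, load_i)
      gi <- geno_index(new_k)
      counts[i, g] <<- counts[i, g] - 1L
      counts[i, gi] <<- counts[i, gi] + 1L
      events[[length(events) + 1L]] <<- data.frame(
        passage = passage, kind = "single_unit", unit_size = n,
        old_mutant_copies = k_reg[g], new_mutant_copies = new_k,
        advantaged = advantaged
      )
    } else {
      total_k <- sum(row * k_reg)
      slots <- if (total_k > 0L) sample.int(u_i * n, total_k) else integer(0)
      k_new <- tabulate((slots - 1L) %/% n + 1L, nbins = u_i)
      gi <- vapply(k_new, geno_index, integer(1))
      counts[i, ] <<- 0L
      for (g in gi) counts[i, g] <<- counts[i, g] + 1L
      events[[length(events) + 1L]] <<- data.frame(
        passage = passage, kind = "full_redistribution", unit_size = n,
        old_mutant_copies = NA_integer_, new_mutant_copies = NA_integer_,
        advantaged = advantaged
      )
    }
    if (advantaged) prop[i] <<- scenario$advantage_multiplier
    invisible(NULL)
  }
  grow_to_cap <- function(passage) {
    while (size < cap) {
      uniform <- all(prop[seq_len(size)] == prop[1L])
      i <- if (size == 1L) 1L
           else if (uniform) sample.int(size, 1L)
           else sample.int(size, 1L, prob = prop[seq_len(size)])
      if (scenario$reorganization_rate > 0 &&
          runif(1L) < scenario$reorganization_rate) {
        reorganize_cell(i, passage)
      }
      row2 <- 2L * counts[i, ]
      d1 <- rbinom(length(row2), row2, 0.5)
      d2 <- row2 - d1
      if (sum(d1) < 1L) {                # dead daughter: lineage continues as d2
        counts[i, ] <<- d2
      } else if (sum(d2) < 1L) {
        counts[i, ] <<- d1
      } else {
        counts[i, ] <<- d1
        size <<- size + 1L
        counts[size, ] <<- d2
        prop[size] <<- prop[i]
      }
    }
    invisible(NULL)
  }
  snapshot_table <- function(passage) {
    sub <- counts[seq_len(size), , drop = FALSE]
    u_cells <- rowSums(sub)
    loads <- as.vector(sub %*% k_reg) / (u_cells * n)
    ro <- readout_unit_clustered(sub, k_reg, rep.int(n, length(k_reg)),
                                 scenario$detection)
    data.frame(
      passage = passage, cell_id = seq_len(size), true_load = loads,
      ro, advantaged = prop[seq_len(size)] > 1
    )
  }
  tabs <- list()
  grow_to_cap(0L)
  tabs[[1L]] <- snapshot_table(0L)
  for (p in seq_len(scenario$n_passages)) {
    keep <- sample.int(size, floor(scenario$bottleneck_fraction * size))
    counts[seq_along(keep), ] <- counts[keep, , drop = FALSE]
    prop[seq_along(keep)] <- prop[keep]
    size <- length(keep)
    if (!is.null(scenario$forced_event_passage) &&
        scenario$forced_event_passage == p) {
      i <- if (size == 1L) 1L else sample.int(size, 1L)
      reorganize_cell(i, p)
    }
    grow_to_cap(p)
    tabs[[p + 1L]] <- snapshot_table(p)
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_event_log()
  structure(
    list(cells = do.call(rbind, tabs), events = ev, scenario = scenario),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s: %d cell records over %d passages, %d event(s)\n",
              x$scenario$model, nrow(x$cells),
              length(unique(x$cells$passage)), nrow(x$events)))
  invisible(x)
}

#' Write or read a synthetic dataset (TSV tables + JSON scenario)
#'
#' `write_dataset()` stores a [generate_scenario()] result in a directory as
#' plain-text files: `cells.tsv`, `events.tsv` and `scenario.json`.
#' `read_dataset()` reconstructs the dataset; the round trip is lossless.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Directory to write to / read from (created if missing).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the `synthetic_dataset`.
#' @examples
#' sc <- clone_scenario("molecule_drift", founder_load = 0.6, copy_number = 40,
#'                      n_passages = 1, population_cap = 100, seed = 7)
#' ds <- generate_scenario(sc)
#' dir <- file.path(tempdir(), "demo-ds")
#' write_dataset(ds, dir)
#' ds2 <- read_dataset(dir)
#' identical(ds$cells, ds2$cells)
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_exact(dataset$cells, file.path(path, "cells.tsv"))
  write_tsv_exact(dataset$events, file.path(path, "events.tsv"))
  sc <- dataset$scenario
  sc_list <- unclass(sc)
  sc_list$detection <- unclass(sc_list$detection)
  jsonlite::write_json(sc_list, file.path(path, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# write a data frame as TSV with doubles rendered at full precision
write_tsv_exact <- function(df, file) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  cells_file <- file.path(path, "cells.tsv")
  events_file <- file.path(path, "events.tsv")
  scenario_file <- file.path(path, "scenario.json")
  for (f in c(cells_file, events_file, scenario_file)) {
    if (!file.exists(f)) stop("missing dataset file: ", f, call. = FALSE)
  }
  cells <- read.delim(cells_file, stringsAsFactors = FALSE)
  need <- c("passage", "cell_id", "true_load", "red_dots", "green_dots",
            "yellow_dots", "advantaged")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop("cells.tsv is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- read.delim(events_file, stringsAsFactors = FALSE,
                       colClasses = c(passage = "integer", kind = "character",
                                      unit_size = "integer",
                                      old_mutant_copies = "integer",
                                      new_mutant_copies = "integer",
                                      advantaged = "logical"))
  sc <- jsonlite::read_json(scenario_file, simplifyVector = TRUE)
  det <- do.call(detection_config, sc$detection[c("efficiency", "mode",
                                                  "rfmt_noise_sd",
                                                  "cell_efficiency_sdlog")])
  args <- sc[setdiff(names(sc), "detection")]
  args$detection <- det
  scenario <- do.call(clone_scenario, args)
  structure(list(cells = cells, events = events, scenario = scenario),
            class = "synthetic_dataset")
}
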