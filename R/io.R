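#' Read and write model input tables
#'
#' Plain-CSV readers/writers for the bundled input types. The species table
#' uses one row per species with the columns documented in
#' [validate_species_table()]; matrices (interaction matrix, raw
#' catchability slices) carry species names as row and column headers;
#' effort schedules have one row per year and one named column per gear.
#'
#' @param path File path.
#' @return `read_species_table()`: a validated species data frame.
#' @export
read_species_table <- function(path) {
  validate_species_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_species_table
#' @param species Species table to write.
#' @export
write_species_table <- function(species, path) {
  utils::write.csv(species, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_species_table
#' @param expected_names Species names the matrix must match (order and
#'   dimension are checked).
#' @export
read_matrix_csv <- function(path, expected_names = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.null(expected_names)) {
    if (!identical(rownames(m), expected_names) ||
        !identical(colnames(m), expected_names)) {
      stop("matrix in ", path, " does not match the species table ",
           "(row/column names must equal the species names, in order)")
    }
  }
  m
}

#' @rdname read_species_table
#' @param m Matrix to write (row and column names kept).
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname read_species_table
#' @export
read_effort_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_species_table
#' @param effort Effort matrix to write.
#' @export
write_effort_csv <- function(effort, path) {
  utils::write.csv(as.data.frame(effort), path, row.names = FALSE)
  invisible(path)
}

#' Write a fixture to a directory
#'
#' Writes `species.csv`, `tau.csv`, `gears.csv` and `config.yaml` (predation
#' parameters, other food, manifest) so a model can be assembled later with
#' [read_community_config()].
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_species_table(fixture$species, file.path(dir, "species.csv"))
  write_matrix_csv(fixture$tau, file.path(dir, "tau.csv"))
  utils::write.csv(fixture$gears, file.path(dir, "gears.csv"), row.names = FALSE)
  cfg <- list(
    species = "species.csv", tau = "tau.csv", gears = "gears.csv",
    pred = unclass(fixture$pred), n_l = fixture$manifest$n_l,
    phi_min = 0.1, manifest = fixture$manifest)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Assemble a community model from a configuration directory
#'
#' Reads `config.yaml` (as written by [write_fixture()]) plus the CSV
#' tables it references and assembles a [CommunityParams-class].
#'
#' @param dir Directory containing `config.yaml`.
#' @return A [CommunityParams-class] object.
#' @export
read_community_config <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) stop("no config.yaml in ", dir)
  cfg <- yaml::read_yaml(cfg_path)
  species <- read_species_table(file.path(dir, cfg$species))
  tau <- read_matrix_csv(file.path(dir, cfg$tau),
                         expected_names = species$species)
  gears <- utils::read.csv(file.path(dir, cfg$gears), stringsAsFactors = FALSE)
  pred <- do.call(pred_params, cfg$pred[c("mu", "sigma", "g0", "other")])
  community_params(species, gears = gears, tau = tau, pred = pred,
                   n_l = cfg$n_l %||% 32L, phi_min = cfg$phi_min %||% 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy long-format export of a simulation
#'
#' Flattens a [SimOutput-class] to rows `(step, year, species, class,
#' variable, value)`; variables are `N`, `M2` and `catch_<gear>` (catch
#' weight per gear). Zero rows are kept so the round trip is exact.
#'
#' @param output [SimOutput-class].
#' @param params Matching [CommunityParams-class].
#' @return A long-format data frame.
#' @export
sim_output_table <- function(output, params) {
  n_l <- dim(output@N)[1]; n_s <- dim(output@N)[2]
  n_steps <- dim(output@N)[3]; H <- dim(output@Catch)[3]
  spy <- round(1 / output@dt)
  base <- expand.grid(class = seq_len(n_l),
                      species = params@species$species,
                      step = seq_len(n_steps), stringsAsFactors = FALSE)
  base$year <- (base$step - 1L) %/% spy + 1L
  blocks <- list(
    cbind(base, variable = "N", value = as.vector(output@N)),
    cbind(base, variable = "M2", value = as.vector(output@M2))
  )
  for (k in seq_len(H)) {
    blocks[[length(blocks) + 1L]] <- cbind(
      base, variable = paste0("catch_", output@gear_names[k]),
      value = as.vector(output@Catch[, , k, ]))
  }
  out <- do.call(rbind, blocks)
  out[, c("step", "year", "species", "class", "variable", "value")]
}

#' @rdname sim_output_table
#' @param path CSV file to write to / read from.
#' @export
write_sim_output <- function(output, params, path) {
  utils::write.csv(sim_output_table(output, params), path, row.names = FALSE)
  invisible(path)
}

#' Rebuild the per-step arrays from a tidy simulation CSV
#'
#' Inverse of [write_sim_output()] for the array components (`N`, `M2`,
#' `Catch`); recruitment and effort are not stored in the tidy file.
#'
#' @param path CSV written by [write_sim_output()].
#' @return List with arrays `N`, `M2`, `Catch` and the gear names.
#' @export
read_sim_output <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  species <- unique(df$species)
  n_s <- length(species)
  n_l <- max(df$class)
  n_steps <- max(df$step)
  grab <- function(variable) {
    sub <- df[df$variable == variable, ]
    sub <- sub[order(sub$step, match(sub$species, species), sub$class), ]
    array(sub$value, c(n_l, n_s, n_steps))
  }
  gear_vars <- unique(df$variable[startsWith(df$variable, "catch_")])
  Catch <- array(0, c(n_l, n_s, length(gear_vars), n_steps))
  for (k in seq_along(gear_vars)) Catch[, , k, ] <- grab(gear_vars[k])
  list(N = grab("N"), M2 = grab("M2"), Catch = Catch,
       gear_names = sub("^catch_", "", gear_vars))
}
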