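# Plain-text writers and readers for the package's data dialects. Headers
# carry the generating parameters as comment lines for provenance.

#' Write a sensorgram set as CSV
#'
#' Columns: `time_s`, `response_RU`, `concentration_M`, `phase`; one block
#' per curve.
#'
#' @param sgs list of `sensorgram` objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sensorgram_csv <- function(sgs, path) {
  tabs <- lapply(sgs, function(sg)
    data.frame(time_s = sg$time, response_RU = sg$response,
               concentration_M = analyte_conc(sg), phase = sg$phase))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a sensorgram CSV written by [write_sensorgram_csv()]
#'
#' @param path input file
#' @return list of `sensorgram` objects, one per concentration block
#' @export
read_sensorgram_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(lapply(split(d, d$concentration_M), function(b)
    new_sensorgram(b$time_s, b$response_RU, b$phase,
                   b$concentration_M[1L])),
    class = c("sensorgram_set", "list"))
}

#' Write a relaxation dataset as TSV
#'
#' @param records data frame from [gen_relaxation_dataset()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_relaxation_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a relaxation TSV
#' @param path input file
#' @return relaxation data frame
#' @export
read_relaxation_tsv <- function(path) utils::read.delim(path)

#' Write a scattering curve as 3-column q/I/sigma text
#'
#' @param curve a `scattering_curve`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_saxs_dat <- function(curve, path) {
  utils::write.table(
    data.frame(q = curve$q, I = curve$I, sigma = curve$sigma),
    path, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 3-column q/I/sigma scattering file
#' @param path input file
#' @return a `scattering_curve`
#' @export
read_saxs_dat <- function(path) {
  d <- utils::read.table(path, col.names = c("q", "I", "sigma"),
                         comment.char = "#")
  scattering_curve(d$q, d$I, d$sigma)
}

#' Write a bead model as plain xyz (one pseudo-atom per bead, Angstrom)
#'
#' @param model a [bead_model()]
#' @param path output file
#' @param element element label written for every bead
#' @return `path`, invisibly
#' @export
write_beads_xyz <- function(model, path, element = "C") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(model$coords)), "bead model"), con)
  writeLines(sprintf("%s %.4f %.4f %.4f", element, model$coords[, 1L],
                     model$coords[, 2L], model$coords[, 3L]), con)
  invisible(path)
}

#' Read a plain xyz bead model
#' @param path input file
#' @return a [bead_model()]
#' @export
read_beads_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1L])
  parts <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+"))
  bead_model(apply(parts[, 2:4, drop = FALSE], 2L, as.numeric))
}

#' Write a melt curve as CSV
#'
#' Columns: `temperature_C`, `fluorescence`, plus one column per metadata
#' entry.
#'
#' @param curve a [melt_curve()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_melt_csv <- function(curve, path) {
  d <- data.frame(temperature_C = curve$temperature,
                  fluorescence = curve$fluorescence)
  cond <- attr(curve, "condition")
  for (nm in names(cond)) d[[nm]] <- cond[[nm]]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a melt-curve CSV
#' @param path input file
#' @return a [melt_curve()] with metadata columns restored as condition
#' @export
read_melt_csv <- function(path) {
  d <- utils::read.csv(path)
  extra <- setdiff(names(d), c("temperature_C", "fluorescence"))
  melt_curve(d$temperature_C, d$fluorescence,
             condition = as.list(d[1L, extra, drop = FALSE]))
}

#' Write a lattice edge list as TSV
#' @param lattice a [build_capsid_graph()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_lattice_edges <- function(lattice, path) {
  utils::write.table(data.frame(from = lattice$edges[, 1L],
                                to = lattice$edges[, 2L]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
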