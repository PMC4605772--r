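# Circuit parameter container and plain-text serialization.

.param_keys <- c(
  "w_ON_AIYL", "w_ON_AIYR", "w_OFF_AIYL", "w_OFF_AIYR",
  "w_AIYL_AIZL", "w_AIYR_AIZR",
  "w_AIZL_SMBDL", "w_AIZL_SMBVL", "w_AIZR_SMBDR", "w_AIZR_SMBVR",
  "w_SMBDL_SMBDL", "w_SMBDR_SMBDR", "w_SMBVL_SMBVL", "w_SMBVR_SMBVR",
  "g_AIY", "g_AIZ",
  "theta_AIYL", "theta_AIYR", "theta_AIZL", "theta_AIZR",
  "theta_SMBDL", "theta_SMBDR", "theta_SMBVL", "theta_SMBVR",
  "w_PG", "w_NMJ", "tau", "T", "v", "N", "M"
)

#' Parameters of the minimal klinotaxis circuit
#'
#' Bundles every constant of one model circuit: the chemical synapse weights
#' of the feedforward wiring (ON/OFF chemosensors onto both AIY interneurons,
#' AIY onto the ipsilateral AIZ, AIZ onto the ipsilateral dorsal and ventral
#' SMB motor neurons, and the SMB self-connections), the two gap-junction
#' conductances, the cell biases, the pattern-generator and neuromuscular
#' weights, the shared membrane time constant, the sensory rise/decay windows
#' \code{N} and \code{M} (in integration steps), the locomotion period
#' \code{T} and the forward speed \code{v}.
#'
#' @param ... named parameter values; every key in
#'   \code{klinfo_param_names()} must be supplied except \code{T}
#'   (default 4.2 s) and \code{v} (default 0.022 cm/s).
#' @param dv_symmetric logical; if \code{TRUE} (default) the dorsal/ventral
#'   symmetry constraint is asserted: biases, self-weights and AIZ->SMB
#'   weights must be identical for the dorsal and ventral cell of each side.
#' @return an object of class \code{circuit_params} (a named numeric vector
#'   with attributes).
#' @examples
#' p <- load_fixture("best")
#' p["g_AIY"]
#' @export
circuit_params <- function(..., dv_symmetric = TRUE) {
  vals <- c(...)
  if (is.list(vals)) vals <- unlist(vals)
  defaults <- c(T = 4.2, v = 0.022)
  for (k in names(defaults))
    if (!k %in% names(vals)) vals[k] <- defaults[[k]]
  missing <- setdiff(.param_keys, names(vals))
  if (length(missing))
    stop("missing circuit parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), .param_keys)
  if (length(extra))
    stop("unknown circuit parameters: ", paste(extra, collapse = ", "))
  vals <- vals[.param_keys]
  validate_circuit_params(vals, dv_symmetric = dv_symmetric)
  structure(vals, class = "circuit_params", dv_symmetric = dv_symmetric)
}

validate_circuit_params <- function(vals, dv_symmetric = TRUE) {
  if (any(!is.finite(vals))) stop("circuit parameters must be finite")
  if (vals["g_AIY"] <= 0 || vals["g_AIZ"] <= 0)
    stop("gap-junction conductances must satisfy g_k > 0")
  for (k in c("tau", "T", "v"))
    if (vals[k] <= 0) stop(k, " must be positive")
  for (k in c("N", "M")) {
    if (vals[k] < 1 || vals[k] != round(vals[k]))
      stop(k, " must be a positive integer number of steps")
  }
  if (dv_symmetric) {
    pairs <- rbind(
      c("theta_SMBDL", "theta_SMBVL"), c("theta_SMBDR", "theta_SMBVR"),
      c("w_SMBDL_SMBDL", "w_SMBVL_SMBVL"), c("w_SMBDR_SMBDR", "w_SMBVR_SMBVR"),
      c("w_AIZL_SMBDL", "w_AIZL_SMBVL"), c("w_AIZR_SMBDR", "w_AIZR_SMBVR")
    )
    for (i in seq_len(nrow(pairs)))
      if (vals[pairs[i, 1]] != vals[pairs[i, 2]])
        stop("dorsal/ventral symmetry violated: ", pairs[i, 1], " != ",
             pairs[i, 2])
  }
  invisible(TRUE)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Klinotaxis circuit parameters",
      if (isTRUE(attr(x, "dv_symmetric"))) "(dorsal/ventral symmetric)", "\n")
  cat(sprintf("  tau = %.3g s, T = %.3g s, v = %.3g cm/s, N = %d, M = %d steps\n",
              x["tau"], x["T"], x["v"], as.integer(x["N"]), as.integer(x["M"])))
  cat(sprintf("  g_AIY = %.3g, g_AIZ = %.3g\n", x["g_AIY"], x["g_AIZ"]))
  w <- x[startsWith(names(x), "w_")]
  cat("  weights:\n")
  print(round(unclass(w), 3))
  th <- x[startsWith(names(x), "theta_")]
  cat("  biases:\n")
  print(round(unclass(th), 3))
  invisible(x)
}

#' Names of all circuit parameters
#' @return character vector of the serialization keys.
#' @export
klinfo_param_names <- function() .param_keys

# Pack a circuit_params object into the flat numeric vector layout the
# compiled engine expects (order must match the enum in src/engine.cpp).
pack_params <- function(params) {
  as.numeric(unclass(params)[.param_keys])
}

#' Read circuit parameters from a flat key-value text file
#'
#' The file dialect is one \code{key value} pair per line, whitespace
#' separated; lines starting with \code{#} are comments.  Keys are exactly
#' the symbol names returned by \code{klinfo_param_names()}.
#'
#' @param path file to read.
#' @param dv_symmetric assert the dorsal/ventral symmetry constraint.
#' @return a \code{circuit_params} object.
#' @export
read_circuit_params <- function(path, dv_symmetric = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(parts, `[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[`, "", 2L))
  names(vals) <- keys
  do.call(circuit_params, c(as.list(vals), dv_symmetric = dv_symmetric))
}

#' Write circuit parameters to a flat key-value text file
#' @param params a \code{circuit_params} object.
#' @param path destination file.
#' @export
write_circuit_params <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  lines <- sprintf("%s %.17g", names(params), as.numeric(params))
  writeLines(lines, path)
  invisible(path)
}

#' Lesion descriptor
#'
#' Flags for in-silico lesions applied during simulation.  Blocking a gap
#' junction zeroes its coupling term while leaving the underlying parameter
#' set untouched.
#'
#' @param block_gap_AIY block the AIY-AIY gap junction.
#' @param block_gap_AIZ block the AIZ-AIZ gap junction.
#' @return an object of class \code{lesion_set}.
#' @export
lesion_set <- function(block_gap_AIY = FALSE, block_gap_AIZ = FALSE) {
  structure(list(block_gap_AIY = isTRUE(block_gap_AIY),
                 block_gap_AIZ = isTRUE(block_gap_AIZ)),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, TRUE)]
  cat("Lesions:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}
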