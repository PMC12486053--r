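# Text-based serialization: datasets as CSV arrays with a JSON sidecar,
# models and ground-truth systems as versioned JSON checkpoints.

mat_to_json <- function(M) {
  if (is.null(M)) return(NULL)
  list(dim = dim(M), data = as.vector(M))
}

mat_from_json <- function(j) {
  if (is.null(j)) return(NULL)
  matrix(unlist(j$data), unlist(j$dim)[1L], unlist(j$dim)[2L])
}

map_to_json <- function(map) {
  if (is.null(map)) return(NULL)
  list(d_in = map$d_in, d_out = map$d_out, mode = map$mode,
       activation = map$activation,
       layers = lapply(map$layers, function(L)
         list(W = mat_to_json(L$W), b = as.vector(L$b))))
}

map_from_json <- function(j) {
  if (is.null(j) || length(j) == 0L) return(NULL)
  structure(list(
    layers = lapply(j$layers, function(L)
      list(W = mat_from_json(L$W), b = unlist(L$b))),
    d_in = j$d_in, d_out = j$d_out,
    activation = j$activation, mode = j$mode), class = "braid_map")
}

sec_to_json <- function(fsec) {
  s <- fsec$sec
  list(state_dim = s$state_dim, d_obs = s$d_obs, d_u = s$d_u,
       d_ft = s$d_ft, role = fsec$role, inputs = fsec$inputs,
       A = map_to_json(s$A), K = map_to_json(s$K),
       Afw = map_to_json(s$Afw), Kfw = map_to_json(s$Kfw),
       D = map_to_json(s$D),
       Cy = map_to_json(fsec$Cy), Cz = map_to_json(fsec$Cz))
}

sec_from_json <- function(j) {
  sec <- structure(list(state_dim = j$state_dim, d_obs = j$d_obs,
                        d_u = j$d_u, d_ft = j$d_ft,
                        A = map_from_json(j$A), K = map_from_json(j$K),
                        Afw = map_from_json(j$Afw),
                        Kfw = map_from_json(j$Kfw),
                        D = map_from_json(j$D)),
                   class = "braid_section")
  list(sec = sec, Cy = map_from_json(j$Cy), Cz = map_from_json(j$Cz),
       role = j$role, inputs = unlist(j$inputs))
}

#' Save a fitted model as a JSON checkpoint
#'
#' Writes all section weights, read-out maps, signal scalers, the
#' preprocessor (if any) and the configuration to a single versioned JSON
#' file that \code{\link{load_braid_model}} restores exactly.
#'
#' @param model a \code{braid_model}.
#' @param path output file path.
#' @export
save_braid_model <- function(model, path) {
  obj <- list(
    schema = "braid-model-1",
    dims = model$dims,
    config = unclass(model$config),
    scalers = model$scalers,
    sections = lapply(model$sections, sec_to_json),
    preprocessor = if (!is.null(model$preprocessor))
      list(sec = sec_to_json(list(sec = model$preprocessor$sec,
                                  role = "preprocessor", inputs = "y")),
           sc_y = model$preprocessor$sc_y, sc_z = model$preprocessor$sc_z))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by \code{save_braid_model}
#' @param path checkpoint file path.
#' @return the restored \code{braid_model}.
#' @export
load_braid_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$schema, "braid-model-1"))
    stop("unrecognized checkpoint schema: ", j$schema %||% "<missing>")
  cfg <- j$config
  cfg$horizons <- as.integer(unlist(cfg$horizons))
  cfg$hweights <- as.numeric(unlist(cfg$hweights))
  cfg$nonlinearity <- lapply(cfg$nonlinearity, as.character)
  config <- do.call(braid_config, cfg[names(cfg) %in%
                                        names(formals(braid_config))])
  fix_sc <- function(sc) if (is.null(sc)) NULL else
    list(mean = unlist(sc$mean), sd = unlist(sc$sd))
  pre <- NULL
  if (!is.null(j$preprocessor)) {
    ps <- sec_from_json(j$preprocessor$sec)
    pre <- list(sec = ps$sec, sc_y = fix_sc(j$preprocessor$sc_y),
                sc_z = fix_sc(j$preprocessor$sc_z))
  }
  structure(list(
    sections = lapply(j$sections, sec_from_json),
    scalers = list(y = fix_sc(j$scalers$y), z = fix_sc(j$scalers$z),
                   u = fix_sc(j$scalers$u)),
    preprocessor = pre,
    dims = lapply(j$dims, function(v) if (is.null(v)) NULL else
      as.integer(v)),
    config = config, history = NULL), class = "braid_model")
}

#' Write a dataset as CSV arrays with a JSON sidecar
#'
#' Creates \code{<prefix>_y.csv}, \code{<prefix>_z.csv},
#' \code{<prefix>_u.csv} and \code{<prefix>_meta.json} (sampling period,
#' seed, fold assignment and, when given, the full ground-truth system for
#' oracle tests).
#'
#' @param dataset a \code{braid_dataset}.
#' @param prefix file path prefix.
#' @param true_model optional \code{braid_sim_system} stored in the sidecar.
#' @export
write_braid_dataset <- function(dataset, prefix, true_model = NULL) {
  wr <- function(M, suff) utils::write.csv(
    as.data.frame(M), paste0(prefix, "_", suff, ".csv"), row.names = FALSE)
  wr(dataset$y, "y"); wr(dataset$z, "z"); wr(dataset$u, "u")
  meta <- list(schema = "braid-dataset-1", dt = dataset$dt,
               seed = dataset$seed, fold_ids = dataset$fold_ids,
               true_model = if (!is.null(true_model))
                 sim_system_to_json(true_model))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Read a dataset written by \code{write_braid_dataset}
#' @param prefix file path prefix used when writing.
#' @return a \code{braid_dataset}; if a ground-truth system was stored it is
#'   attached as attribute \code{"true_model"}.
#' @export
read_braid_dataset <- function(prefix) {
  rd <- function(suff) as.matrix(utils::read.csv(
    paste0(prefix, "_", suff, ".csv")))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = FALSE)
  ds <- braid_dataset(rd("y"), rd("z"), rd("u"), dt = meta$dt,
                      fold_ids = as.integer(unlist(meta$fold_ids)),
                      seed = if (is.null(meta$seed)) NA_integer_ else
                        meta$seed)
  if (!is.null(meta$true_model))
    attr(ds, "true_model") <- sim_system_from_json(meta$true_model)
  ds
}

sim_system_to_json <- function(m) {
  b <- m$behavior
  list(n_x = m$n_x, n_y = m$n_y, n_z = m$n_z, n_u = m$n_u,
       nonlinearity = m$nonlinearity, seed = m$seed,
       A = mat_to_json(m$A), B = mat_to_json(m$B), Cy = mat_to_json(m$Cy),
       Q = mat_to_json(m$Q), P_x = mat_to_json(m$P_x),
       v_sd = m$v_sd, eps_sd = m$eps_sd, input = m$input,
       input_encoder = if (!is.null(m$input_encoder))
         list(P = mat_to_json(m$input_encoder$P), q = m$input_encoder$q),
       behavior = list(type = b$type, a = b$a, b = b$b, r0 = b$r0,
                       p = b$p, q = b$q, signal_var = b$signal_var,
                       C = mat_to_json(b$C), Cr = mat_to_json(b$Cr),
                       Ct = mat_to_json(b$Ct), E = mat_to_json(b$E),
                       C1 = mat_to_json(b$C1), C2 = mat_to_json(b$C2)),
       behavior_specific = if (!is.null(m$behavior_specific))
         list(A3 = mat_to_json(m$behavior_specific$A3),
              K3 = mat_to_json(m$behavior_specific$K3),
              C3 = mat_to_json(m$behavior_specific$C3),
              gain = m$behavior_specific$gain))
}

sim_system_from_json <- function(j) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  b <- j$behavior
  behavior <- list(type = b$type, a = b$a, b = b$b, r0 = b$r0,
                   p = num(b$p), q = num(b$q),
                   signal_var = num(b$signal_var),
                   C = mat_from_json(b$C), Cr = mat_from_json(b$Cr),
                   Ct = mat_from_json(b$Ct), E = mat_from_json(b$E),
                   C1 = mat_from_json(b$C1), C2 = mat_from_json(b$C2))
  behavior <- behavior[!vapply(behavior, is.null, logical(1))]
  structure(list(
    n_x = j$n_x, n_y = j$n_y, n_z = j$n_z, n_u = j$n_u,
    nonlinearity = j$nonlinearity, seed = j$seed,
    A = mat_from_json(j$A), B = mat_from_json(j$B),
    Cy = mat_from_json(j$Cy), Q = mat_from_json(j$Q),
    P_x = mat_from_json(j$P_x),
    v_sd = num(j$v_sd), eps_sd = num(j$eps_sd),
    input = list(pole = j$input$pole, innov_sd = j$input$innov_sd),
    input_encoder = if (!is.null(j$input_encoder))
      list(P = mat_from_json(j$input_encoder$P), q = num(j$input_encoder$q)),
    behavior = behavior,
    behavior_specific = if (!is.null(j$behavior_specific))
      list(A3 = mat_from_json(j$behavior_specific$A3),
           K3 = mat_from_json(j$behavior_specific$K3),
           C3 = mat_from_json(j$behavior_specific$C3),
           gain = j$behavior_specific$gain)),
    class = "braid_sim_system")
}
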