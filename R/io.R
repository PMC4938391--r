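#' File I/O for surfaces, fields and labels
#'
#' The package reads and writes three surfaces of interchange:
#' * GIFTI XML (`.surf.gii` geometry, `.func.gii` per-vertex time series,
#'   `.label.gii` labels) via a lightweight codec supporting ASCII,
#'   Base64Binary and GZipBase64Binary encodings (little-endian);
#' * plain TSV label tables (`vertex_index`, `label`, 0-based);
#' * a single-file array container (`.rds`, a named bundle holding mesh,
#'   field, labels and metadata together).
#'
#' All on-disk vertex indices and labels are 0-based; in-memory objects are
#' 1-based (R convention). Conversion happens here and only here.
#'
#' @name tnlm-io
NULL

#' Read a surface mesh
#'
#' @param path `.surf.gii` GIFTI geometry or `.rds` container.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path) {
  switch(file_kind(path),
    surf_gii = read_gifti_surface(path),
    container = {
      b <- read_container(path)
      if (is.null(b$mesh)) stop("container has no mesh entry", call. = FALSE)
      surface_mesh(b$mesh$vertices, b$mesh$triangles + 1L)
    },
    stop("unrecognized surface format: ", path, call. = FALSE)
  )
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path `.surf.gii` or `.rds` container.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  switch(file_kind(path),
    surf_gii = write_gifti_surface(mesh, path),
    container = write_container(list(mesh = mesh_entry(mesh)), path),
    stop("unrecognized surface format: ", path, call. = FALSE)
  )
  invisible(path)
}

#' Read a per-vertex time-series field
#'
#' @param path `.func.gii` (one map per time point) or `.rds` container.
#' @param mesh optional [surface_mesh()]; when given, the vertex count is
#'   validated against the field.
#' @return a [ts_field()].
#' @export
read_field <- function(path, mesh = NULL) {
  field <- switch(file_kind(path),
    func_gii = read_gifti_field(path),
    container = {
      b <- read_container(path)
      if (is.null(b$field)) stop("container has no field entry",
                                 call. = FALSE)
      ts_field(b$field$data,
               standardized = isTRUE(b$field$standardized),
               zero_var = b$field$zero_var, tr = b$field$tr)
    },
    stop("unrecognized field format: ", path, call. = FALSE)
  )
  if (!is.null(mesh)) check_field_mesh(field, mesh)
  field
}

#' Write a per-vertex time-series field
#'
#' @param field a [ts_field()].
#' @param path `.func.gii` or `.rds` container.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ts_field"))
  switch(file_kind(path),
    func_gii = write_gifti_field(field, path),
    container = write_container(list(field = field_entry(field)), path),
    stop("unrecognized field format: ", path, call. = FALSE)
  )
  invisible(path)
}

#' Read a parcellation / label map
#'
#' @param path `.label.gii`, `.tsv` (`vertex_index`, `label`; 0-based) or
#'   `.rds` container.
#' @return a [parcellation()].
#' @export
read_labels <- function(path) {
  switch(file_kind(path),
    label_gii = read_gifti_labels(path),
    tsv = {
      tab <- utils::read.delim(path, comment.char = "#")
      if (!all(c("vertex_index", "label") %in% names(tab)))
        stop("TSV must have columns vertex_index, label", call. = FALSE)
      labels <- integer(nrow(tab))
      labels[tab$vertex_index + 1L] <- tab$label + 1L
      parcellation(labels, method = "file")
    },
    container = {
      b <- read_container(path)
      if (is.null(b$labels)) stop("container has no labels entry",
                                  call. = FALSE)
      parcellation(b$labels$labels + 1L, K = b$labels$K,
                   method = b$labels$method %||% "file")
    },
    stop("unrecognized label format: ", path, call. = FALSE)
  )
}

#' Write a parcellation / label map
#'
#' @param parcellation a [parcellation()] (or integer label vector).
#' @param path `.label.gii`, `.tsv` or `.rds` container.
#' @export
write_labels <- function(parcellation, path) {
  labels <- parcel_labels(parcellation)
  switch(file_kind(path),
    label_gii = write_gifti_labels(labels, path),
    tsv = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("# tnlm labels; vertex_index and label are 0-based",
                   "vertex_index\tlabel"), con)
      utils::write.table(
        data.frame(vertex_index = seq_along(labels) - 1L,
                   label = labels - 1L),
        con, sep = "\t", row.names = FALSE, col.names = FALSE,
        quote = FALSE)
    },
    container = write_container(list(labels = labels_entry(parcellation)),
                                path),
    stop("unrecognized label format: ", path, call. = FALSE)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

file_kind <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.surf\\.gii$", lower)) "surf_gii"
  else if (grepl("\\.func\\.gii$", lower)) "func_gii"
  else if (grepl("\\.label\\.gii$", lower)) "label_gii"
  else if (grepl("\\.tsv$", lower)) "tsv"
  else if (grepl("\\.rds$", lower)) "container"
  else "unknown"
}

check_field_mesh <- function(field, mesh) {
  if (field$n_vertices != mesh$n_vertices)
    stop("field has ", field$n_vertices, " vertices but mesh has ",
         mesh$n_vertices, call. = FALSE)
  invisible(TRUE)
}

#' Lightweight mesh checksum
#'
#' Cheap fingerprint (vertex/triangle counts plus coordinate and index
#' sums) recorded in containers so a field can be validated against the
#' mesh it was sampled on.
#'
#' @param mesh a [surface_mesh()].
#' @return character checksum.
#' @export
mesh_checksum <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  sprintf("n%d.t%d.v%.6e.i%d", mesh$n_vertices, nrow(mesh$triangles),
          sum(mesh$vertices * rep(c(1, 3, 7), each = mesh$n_vertices)),
          sum(as.numeric(mesh$triangles)) %% 2147483647)
}

## ---- array container (single-file named bundle) ----

mesh_entry <- function(mesh) {
  list(vertices = mesh$vertices, triangles = mesh$triangles - 1L,
       index_base = 0L, checksum = mesh_checksum(mesh))
}

field_entry <- function(field, mesh = NULL) {
  list(data = field$data, standardized = field$standardized,
       zero_var = field$zero_var, tr = field$tr,
       mesh_checksum = if (is.null(mesh)) NULL else mesh_checksum(mesh))
}

labels_entry <- function(p) {
  labels <- parcel_labels(p)
  list(labels = labels - 1L, index_base = 0L,
       K = if (inherits(p, "parcellation")) p$K else length(unique(labels)),
       method = if (inherits(p, "parcellation")) p$method else "manual")
}

#' Write / read the single-file array container
#'
#' A named bundle (`mesh`, `field`, `labels`, plus free-form metadata)
#' serialized to one `.rds` file. Writing the result of a read back out
#' reproduces the file byte-identically. All indices inside the container
#' are 0-based (recorded in each entry's `index_base`).
#'
#' @param entries named list of entries (see [write_bundle()] for the
#'   high-level interface).
#' @param path `.rds` path.
#' @return `read_container` returns the named list.
#' @keywords internal
#' @export
write_container <- function(entries, path) {
  entries$format <- "tnlm-container"
  entries$container_version <- 1L
  entries$index_base <- 0L
  entries <- entries[order(names(entries))]
  saveRDS(entries, path, version = 3L, compress = "gzip")
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format, "tnlm-container"))
    stop(path, " is not a tnlm array container", call. = FALSE)
  b
}

#' Write a simulation bundle (mesh + field + truth labels) to one container
#'
#' @param sim a [simulate_quadrant_field()] result.
#' @param mesh the [surface_mesh()] the field lives on.
#' @param path `.rds` container path.
#' @export
write_bundle <- function(sim, mesh, path) {
  write_container(list(
    mesh = mesh_entry(mesh),
    field = field_entry(sim$field, mesh),
    labels = labels_entry(sim$region),
    quadrant_labels = labels_entry(sim$quadrant),
    sim_spec = unclass(sim$spec)
  ), path)
}

## ---- GIFTI codec ----

gifti_read_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L)
    stop(path, ": no DataArray elements found", call. = FALSE)
  lapply(arrays, function(da) {
    att <- xml2::xml_attrs(da)
    dims <- as.integer(att[grepl("^Dim[0-9]$", names(att))])
    data_node <- xml2::xml_find_first(da, ".//Data")
    txt <- xml2::xml_text(data_node)
    dtype <- att[["DataType"]]
    vals <- switch(att[["Encoding"]],
      ASCII = {
        v <- scan(text = txt, what = numeric(), quiet = TRUE)
        if (dtype %in% c("NIFTI_TYPE_INT32", "NIFTI_TYPE_UINT8"))
          as.integer(v) else v
      },
      Base64Binary = decode_binary(jsonlite::base64_dec(gsub("\\s", "", txt)),
                                   dtype),
      GZipBase64Binary = decode_binary(
        memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)),
                      type = "gzip"),
        dtype),
      stop("unsupported GIFTI encoding: ", att[["Encoding"]], call. = FALSE)
    )
    order_rowmajor <- !identical(att[["ArrayIndexingOrder"]],
                                 "ColumnMajorOrder")
    mat <- if (length(dims) >= 2L) {
      matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = order_rowmajor)
    } else {
      matrix(vals, ncol = 1L)
    }
    list(intent = att[["Intent"]], data = mat, doc = doc, node = da)
  })
}

decode_binary <- function(raw, dtype) {
  switch(dtype,
    NIFTI_TYPE_FLOAT32 = readBin(raw, "double", n = length(raw) / 4L,
                                 size = 4L, endian = "little"),
    NIFTI_TYPE_FLOAT64 = readBin(raw, "double", n = length(raw) / 8L,
                                 size = 8L, endian = "little"),
    NIFTI_TYPE_INT32 = readBin(raw, "integer", n = length(raw) / 4L,
                               size = 4L, endian = "little"),
    NIFTI_TYPE_UINT8 = as.integer(raw),
    stop("unsupported GIFTI data type: ", dtype, call. = FALSE)
  )
}

read_gifti_surface <- function(path) {
  arrays <- gifti_read_arrays(path)
  intents <- vapply(arrays, `[[`, "", "intent")
  pi <- match("NIFTI_INTENT_POINTSET", intents)
  ti <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(pi) || is.na(ti))
    stop(path, ": need POINTSET and TRIANGLE data arrays", call. = FALSE)
  surface_mesh(arrays[[pi]]$data, arrays[[ti]]$data + 1L)
}

read_gifti_field <- function(path) {
  arrays <- gifti_read_arrays(path)
  keep <- vapply(arrays, function(a)
    a$intent %in% c("NIFTI_INTENT_NONE", "NIFTI_INTENT_TIME_SERIES"), TRUE)
  arrays <- arrays[keep]
  if (length(arrays) == 0L)
    stop(path, ": no functional data arrays", call. = FALSE)
  X <- do.call(cbind, lapply(arrays, function(a) a$data[, 1L]))
  meta <- gifti_metadata(arrays[[1L]]$doc)
  std <- identical(meta[["standardized"]], "1")
  f <- ts_field(X, standardized = std,
                tr = as.numeric(meta[["tr"]] %||% NA))
  if (std) {
    # recover the zero-variance flags from the data itself (float32 storage)
    f$zero_var <- rowSums(f$data != 0) == 0L
  }
  f
}

read_gifti_labels <- function(path) {
  arrays <- gifti_read_arrays(path)
  intents <- vapply(arrays, `[[`, "", "intent")
  li <- match("NIFTI_INTENT_LABEL", intents)
  if (is.na(li)) stop(path, ": no LABEL data array", call. = FALSE)
  parcellation(as.integer(arrays[[li]]$data[, 1L]) + 1L, method = "file")
}

gifti_metadata <- function(doc) {
  md <- xml2::xml_find_all(doc, "/GIFTI/MetaData/MD")
  vals <- vapply(md, function(m)
    xml2::xml_text(xml2::xml_find_first(m, "Value")), "")
  names(vals) <- vapply(md, function(m)
    xml2::xml_text(xml2::xml_find_first(m, "Name")), "")
  as.list(vals)
}

gifti_skeleton <- function(n_arrays, meta = list()) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(n_arrays))
  md <- xml2::xml_add_child(doc, "MetaData")
  meta <- c(list(index_base = "0"), meta)
  for (nm in names(meta)) {
    m <- xml2::xml_add_child(md, "MD")
    xml2::xml_add_child(m, "Name", nm)
    xml2::xml_add_child(m, "Value", as.character(meta[[nm]]))
  }
  doc
}

gifti_add_array <- function(doc, mat, intent, dtype, fmt = "%.9g") {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = dtype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = "2",
    Dim0 = as.character(nrow(mat)), Dim1 = as.character(ncol(mat)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  txt <- paste(apply(mat, 1L, function(r)
    paste(sprintf(fmt, r), collapse = " ")), collapse = "\n")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

write_gifti_surface <- function(mesh, path) {
  doc <- gifti_skeleton(2L)
  gifti_add_array(doc, mesh$vertices, "NIFTI_INTENT_POINTSET",
                  "NIFTI_TYPE_FLOAT32")
  gifti_add_array(doc, mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                  "NIFTI_TYPE_INT32", fmt = "%d")
  xml2::write_xml(doc, path)
  invisible(path)
}

write_gifti_field <- function(field, path) {
  meta <- list(standardized = if (field$standardized) "1" else "0")
  if (!is.na(field$tr)) meta$tr <- format(field$tr)
  doc <- gifti_skeleton(field$n_time, meta)
  for (tau in seq_len(field$n_time))
    gifti_add_array(doc, field$data[, tau, drop = FALSE],
                    "NIFTI_INTENT_TIME_SERIES", "NIFTI_TYPE_FLOAT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

write_gifti_labels <- function(labels, path) {
  doc <- gifti_skeleton(1L)
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (key in sort(unique(labels)) - 1L)
    xml2::xml_add_child(lt, "Label", paste0("parcel_", key),
                        Key = as.character(key))
  gifti_add_array(doc, matrix(labels - 1L, ncol = 1L),
                  "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32", fmt = "%d")
  xml2::write_xml(doc, path)
  invisible(path)
}
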