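# Minimal DICOM-RT-Plan I/O: explicit-VR little-endian only, covering the
# subset a static / step-and-shoot plan needs (beam sequence with jaw, MLC,
# gantry, SSD and per-beam meterset). Anything else — other transfer
# syntaxes, dynamic arcs — is rejected with a named error rather than
# guessed at.

.SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_ROOT <- "1.2.826.0.1.3680043.10.9000"

.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.str_bytes <- function(s, pad = as.raw(0x20)) {
  b <- charToRaw(s)
  if (length(b) %% 2L) b <- c(b, pad)
  b
}

.element <- function(group, elem, vr, bytes) {
  if (vr %in% .vr_long) {
    c(.u16(group), .u16(elem), charToRaw(vr), raw(2L), .u32(length(bytes)), bytes)
  } else {
    c(.u16(group), .u16(elem), charToRaw(vr), .u16(length(bytes)), bytes)
  }
}

.el_str <- function(group, elem, vr, s, pad = as.raw(0x20)) {
  .element(group, elem, vr, .str_bytes(s, pad))
}

.ds_multi <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

.item <- function(bytes) c(.u16(0xFFFE), .u16(0xE000), .u32(length(bytes)), bytes)

.sq <- function(group, elem, items) {
  body <- do.call(c, lapply(items, .item))
  .element(group, elem, "SQ", body)
}

#' Write a plan as a DICOM-RT-Plan file
#'
#' Emits an explicit-VR little-endian RT Plan with one static control point
#' per beam: jaw positions (ASYMX/ASYMY), optional MLC bank positions
#' (MLCY, bank-1 then bank-2 edges), gantry angle, source-surface distance
#' and per-beam meterset.
#'
#' @param plan An [rt_plan()].
#' @param path Output path (`.dcm`).
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path) {
  stopifnot(inherits(plan, "rt_plan"))
  nf <- length(plan$fields)
  sop_uid <- paste0(.UID_ROOT, ".", format(nf), ".",
                    abs(sum(utf8ToInt(plan$id %||% "plan"))))

  meta_elems <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .el_str(0x0002, 0x0002, "UI", .SOP_RTPLAN, as.raw(0)),
    .el_str(0x0002, 0x0003, "UI", sop_uid, as.raw(0)),
    .el_str(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE, as.raw(0)),
    .el_str(0x0002, 0x0012, "UI", paste0(.UID_ROOT, ".1"), as.raw(0))
  )
  meta <- c(.element(0x0002, 0x0000, "UL", .u32(length(meta_elems))), meta_elems)

  ref_beams <- lapply(seq_len(nf), function(i) {
    c(.el_str(0x300A, 0x0086, "DS", .ds_multi(plan$fields[[i]]$mu)),
      .el_str(0x300C, 0x0006, "IS", format(i)))
  })
  frac_item <- c(
    .el_str(0x300A, 0x0078, "IS", "1"),
    .sq(0x300C, 0x0004, ref_beams)
  )

  beams <- lapply(seq_len(nf), function(i) {
    f <- plan$fields[[i]]
    bld <- list(
      c(.el_str(0x300A, 0x00B8, "CS", "ASYMX"),
        .el_str(0x300A, 0x011C, "DS", .ds_multi(f$jaw_x)))
    )
    bld <- c(bld, list(
      c(.el_str(0x300A, 0x00B8, "CS", "ASYMY"),
        .el_str(0x300A, 0x011C, "DS", .ds_multi(f$jaw_y)))
    ))
    if (!is.null(f$mlc_aperture)) {
      bld <- c(bld, list(
        c(.el_str(0x300A, 0x00B8, "CS", "MLCY"),
          .el_str(0x300A, 0x011C, "DS",
                  .ds_multi(c(f$mlc_aperture[, 1L], f$mlc_aperture[, 2L]))))
      ))
    }
    cp <- c(
      .el_str(0x300A, 0x0112, "IS", "0"),
      .sq(0x300A, 0x011A, bld),
      .el_str(0x300A, 0x011E, "DS", .ds_multi(f$gantry_angle)),
      .el_str(0x300A, 0x0130, "DS", .ds_multi(f$ssd))
    )
    c(
      .el_str(0x300A, 0x00C0, "IS", format(i)),
      .el_str(0x300A, 0x00C2, "LO", f$id %||% sprintf("field_%02d", i)),
      .el_str(0x300A, 0x00C4, "CS", "STATIC"),
      .el_str(0x300A, 0x0110, "IS", "1"),
      .sq(0x300A, 0x0111, list(cp))
    )
  })

  dataset <- c(
    .el_str(0x0008, 0x0016, "UI", .SOP_RTPLAN, as.raw(0)),
    .el_str(0x0008, 0x0018, "UI", sop_uid, as.raw(0)),
    .el_str(0x0008, 0x0060, "CS", "RTPLAN"),
    .el_str(0x300A, 0x0002, "SH", plan$id %||% "plan"),
    .sq(0x300A, 0x0070, list(frac_item)),
    .sq(0x300A, 0x00B0, beams)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

.rd_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
.rd_u32 <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

# parse one data element at pos; returns list(group, elem, vr, value, pos)
.parse_element <- function(buf, pos) {
  group <- .rd_u16(buf, pos)
  elem <- .rd_u16(buf, pos + 2L)
  if (group == 0xFFFE) {  # item / delimiter
    len <- .rd_u32(buf, pos + 4L)
    return(list(group = group, elem = elem, vr = NA_character_,
                len = len, pos = pos + 8L))
  }
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  if (vr %in% .vr_long) {
    len <- .rd_u32(buf, pos + 8L)
    body <- pos + 12L
  } else {
    len <- .rd_u16(buf, pos + 6L)
    body <- pos + 8L
  }
  if (vr == "SQ") {
    items <- list()
    if (len == 4294967295) {  # undefined length
      p <- body
      repeat {
        it <- .parse_element(buf, p)
        if (it$group == 0xFFFE && it$elem == 0xE0DD) { p <- it$pos; break }
        parsed <- .parse_item(buf, it)
        items[[length(items) + 1L]] <- parsed$elements
        p <- parsed$pos
      }
      return(list(group = group, elem = elem, vr = vr, value = items, pos = p))
    }
    p <- body
    while (p < body + len) {
      it <- .parse_element(buf, p)
      parsed <- .parse_item(buf, it)
      items[[length(items) + 1L]] <- parsed$elements
      p <- parsed$pos
    }
    return(list(group = group, elem = elem, vr = vr, value = items, pos = p))
  }
  value <- if (len > 0) buf[body:(body + len - 1L)] else raw(0L)
  list(group = group, elem = elem, vr = vr, value = value, pos = body + len)
}

# parse the elements of one sequence item (it = parsed item header)
.parse_item <- function(buf, it) {
  stopifnot(it$group == 0xFFFE, it$elem == 0xE000)
  elements <- list()
  p <- it$pos
  end <- if (it$len == 4294967295) NA else it$pos + it$len
  repeat {
    if (!is.na(end) && p >= end) break
    e <- .parse_element(buf, p)
    if (e$group == 0xFFFE && e$elem == 0xE00D) { p <- e$pos; break }
    elements[[sprintf("%04X,%04X", e$group, e$elem)]] <- e
    p <- e$pos
  }
  list(elements = elements, pos = p)
}

.parse_dataset <- function(buf, pos, end) {
  elements <- list()
  p <- pos
  while (p < end) {
    e <- .parse_element(buf, p)
    elements[[sprintf("%04X,%04X", e$group, e$elem)]] <- e
    p <- e$pos
  }
  elements
}

.el_string <- function(elements, tag) {
  e <- elements[[tag]]
  if (is.null(e)) return(NULL)
  v <- e$value[e$value != as.raw(0)]
  trimws(rawToChar(v))
}
.el_numbers <- function(elements, tag) {
  s <- .el_string(elements, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}

#' Read a DICOM-RT-Plan subset
#'
#' Parses an explicit-VR little-endian RT Plan and returns one
#' [field_spec()] per beam (jaws, MLC leaf positions, gantry angle, SSD,
#' meterset). Dynamic modulation is rejected: the supported machine
#' delivers step-and-shoot IMRT and 3-D conformal beams only, so a beam
#' typed `DYNAMIC` or whose control points move the gantry raises a
#' `seccheck_unsupported_modality` error. A beam without a meterset raises
#' a parse error naming the beam.
#'
#' @param path Path to the `.dcm` file.
#' @return An [rt_plan()] (fields only; TPS comparison values are not part
#'   of an RT Plan and stay `NULL`).
#' @export
read_rtplan <- function(path) {
  if (!file.exists(path)) {
    stop_seccheck(sprintf("no such file: %s", path), "seccheck_io_error")
  }
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM") {
    stop_seccheck("not a DICOM part-10 file (missing DICM magic)",
                  "seccheck_parse_error")
  }
  # file meta group: (0002,0000) UL group length
  meta0 <- .parse_element(buf, 133L)
  if (meta0$group != 2L || meta0$elem != 0L) {
    stop_seccheck("malformed file meta information", "seccheck_parse_error")
  }
  meta_len <- .rd_u32(meta0$value, 1L)
  meta <- .parse_dataset(buf, meta0$pos, meta0$pos + meta_len)
  ts <- .el_string(meta, "0002,0010")
  if (!identical(ts, .TS_EXPLICIT_LE)) {
    stop_seccheck(sprintf("unsupported transfer syntax %s (explicit-VR little-endian only)", ts),
                  "seccheck_parse_error")
  }
  ds <- .parse_dataset(buf, meta0$pos + meta_len, length(buf) + 1L)

  beam_sq <- ds[["300A,00B0"]]
  if (is.null(beam_sq)) {
    stop_seccheck("RT Plan has no beam sequence", "seccheck_parse_error")
  }
  # metersets from the fraction-group referenced-beam sequence
  mu_by_beam <- list()
  fg <- ds[["300A,0070"]]
  if (!is.null(fg)) {
    for (fg_item in fg$value) {
      rb <- fg_item[["300C,0004"]]
      if (is.null(rb)) next
      for (r in rb$value) {
        num <- .el_string(r, "300C,0006")
        ms <- .el_numbers(r, "300A,0086")
        if (!is.null(num) && !is.null(ms)) mu_by_beam[[num]] <- ms
      }
    }
  }

  fields <- lapply(beam_sq$value, function(b) {
    num <- .el_string(b, "300A,00C0")
    name <- .el_string(b, "300A,00C2") %||% paste0("beam_", num)
    btype <- .el_string(b, "300A,00C4")
    if (identical(btype, "DYNAMIC")) {
      stop_seccheck(
        sprintf("beam %s is DYNAMIC: dynamic arcs are not supported (step-and-shoot and 3-D conformal only)", num),
        "seccheck_unsupported_modality"
      )
    }
    cps <- b[["300A,0111"]]
    if (is.null(cps) || !length(cps$value)) {
      stop_seccheck(sprintf("beam %s has no control points", num),
                    "seccheck_parse_error")
    }
    gantries <- unlist(lapply(cps$value, .el_numbers, tag = "300A,011E"))
    if (length(unique(round(gantries, 6))) > 1L) {
      stop_seccheck(
        sprintf("beam %s rotates the gantry across control points: arcs are not supported", num),
        "seccheck_unsupported_modality"
      )
    }
    cp <- cps$value[[1L]]
    jaw_x <- jaw_y <- NULL
    mlc <- NULL
    bld <- cp[["300A,011A"]]
    if (!is.null(bld)) {
      for (dev in bld$value) {
        dtype <- .el_string(dev, "300A,00B8")
        pos <- .el_numbers(dev, "300A,011C")
        if (dtype %in% c("X", "ASYMX")) jaw_x <- pos
        else if (dtype %in% c("Y", "ASYMY")) jaw_y <- pos
        else if (dtype %in% c("MLCX", "MLCY")) {
          n <- length(pos) / 2
          mlc <- cbind(pos[seq_len(n)], pos[n + seq_len(n)])
        }
      }
    }
    if (is.null(jaw_x) || is.null(jaw_y)) {
      stop_seccheck(sprintf("beam %s lacks jaw positions", num),
                    "seccheck_parse_error")
    }
    mu <- mu_by_beam[[num]]
    if (is.null(mu)) {
      stop_seccheck(sprintf("beam %s has no meterset (MU)", num),
                    "seccheck_parse_error")
    }
    ssd <- .el_numbers(cp, "300A,0130")
    field_spec(jaw_x = jaw_x, jaw_y = jaw_y, mlc_aperture = mlc,
               gantry_angle = gantries[1L] %||% 0, mu = mu,
               ssd = ssd %||% 1335, id = name)
  })
  rt_plan(fields = fields, id = .el_string(ds, "300A,0002") %||% "plan")
}
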