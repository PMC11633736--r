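# TIFF tag ids used by the float writer/reader
.tiffTagNames <- c(
    "256" = "ImageWidth", "257" = "ImageLength", "258" = "BitsPerSample",
    "259" = "Compression", "262" = "PhotometricInterpretation",
    "270" = "ImageDescription", "273" = "StripOffsets",
    "277" = "SamplesPerPixel", "278" = "RowsPerStrip",
    "279" = "StripByteCounts", "282" = "XResolution",
    "283" = "YResolution", "296" = "ResolutionUnit",
    "339" = "SampleFormat")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")
.f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                             endian = "little")

#' Write a multi-page 32-bit float TIFF
#'
#' Minimal baseline TIFF writer producing one 32-bit IEEE float page per
#' image plane (SampleFormat 3, uncompressed, single strip), with the
#' physical pixel size stored both in the resolution tags (pixels per
#' centimeter) and, at full precision, in a YAML block in the
#' ImageDescription tag together with the channel names and any extra
#' metadata. Values are stored as-is (no [0, 1] rescaling), so images
#' round-trip losslessly at float32 precision; files open in ImageJ and
#' tifffile.
#'
#' @param x a matrix, a \code{[y, x, page]} array, an
#'   [ImagePair-class] (pages IR, Raman) or a [ConcentrationMap-class]
#'   (one page per species).
#' @param path output path.
#' @param pixelSize pixel size (um); taken from the object when it carries
#'   one.
#' @param channels character vector of page names.
#' @param meta named list of extra metadata for the description block.
#' @return invisibly, the path.
#' @export
writeImageTiff <- function(x, path, pixelSize = NULL, channels = NULL,
                           meta = list()) {
    if (is(x, "ImagePair")) {
        pages <- list(x@ir, x@raman)
        if (is.null(channels)) channels <- c("IR", "Raman")
        if (is.null(pixelSize)) pixelSize <- x@pixelSize
    } else if (is(x, "ConcentrationMap")) {
        pages <- lapply(seq_along(x@species), function(s) x@grid[, , s])
        if (is.null(channels)) channels <- x@species
        if (is.null(pixelSize)) pixelSize <- x@pixelSize
    } else if (is.matrix(x)) {
        pages <- list(x)
    } else if (is.array(x) && length(dim(x)) == 3L) {
        pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
    } else stop("unsupported image object")
    if (is.null(pixelSize)) pixelSize <- 1
    if (is.null(channels)) channels <- paste0("page", seq_along(pages))
    desc <- yaml::as.yaml(c(list(pixel_size_um = pixelSize,
                                 channels = as.list(channels)), meta))
    descRaw <- c(charToRaw(desc), as.raw(0))
    if (length(descRaw) %% 2 == 1) descRaw <- c(descRaw, as.raw(0))
    # resolution: pixels per centimeter as a rational
    resRaw <- c(.u32(1e7), .u32(max(1, round(pixelSize * 1e3))))

    header <- c(charToRaw("II"), .u16(42))
    chunks <- list()
    nIfdEntries <- 14L
    ifdSize <- 2L + nIfdEntries * 12L + 4L
    stripLens <- vapply(pages, function(m) 4L * length(m), integer(1))
    chunkLens <- stripLens + length(descRaw) + 16L + ifdSize
    chunkStarts <- 8L + c(0L, cumsum(chunkLens))[seq_along(pages)]
    ifdOffsets <- chunkStarts + stripLens + length(descRaw) + 16L
    for (p in seq_along(pages)) {
        m <- pages[[p]]
        h <- nrow(m); w <- ncol(m)
        strip <- .f32(as.vector(t(m)))
        stripOff <- chunkStarts[p]
        descOff <- stripOff + length(strip)
        xresOff <- descOff + length(descRaw)
        yresOff <- xresOff + 8L
        ifdOff <- ifdOffsets[p]
        nextIfd <- if (p < length(pages)) ifdOffsets[p + 1] else 0L
        entry <- function(tag, type, count, value, isOffset = FALSE) {
            val <- if (type == 3L && !isOffset)
                c(.u16(value), .u16(0)) else .u32(value)
            c(.u16(tag), .u16(type), .u32(count), val)
        }
        ifd <- c(
            .u16(nIfdEntries),
            entry(256L, 4L, 1L, w),
            entry(257L, 4L, 1L, h),
            entry(258L, 3L, 1L, 32L),
            entry(259L, 3L, 1L, 1L),
            entry(262L, 3L, 1L, 1L),
            entry(270L, 2L, length(descRaw), descOff, isOffset = TRUE),
            entry(273L, 4L, 1L, stripOff),
            entry(277L, 3L, 1L, 1L),
            entry(278L, 4L, 1L, h),
            entry(279L, 4L, 1L, length(strip)),
            entry(282L, 5L, 1L, xresOff, isOffset = TRUE),
            entry(283L, 5L, 1L, yresOff, isOffset = TRUE),
            entry(296L, 3L, 1L, 3L),
            entry(339L, 3L, 1L, 3L),
            .u32(nextIfd))
        # layout: [strip][description][xres rational][yres rational][IFD]
        chunks[[p]] <- c(strip, descRaw, resRaw, resRaw, ifd)
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(header, .u32(ifdOffsets[1])), con)
    for (ch in chunks) writeBin(ch, con)
    invisible(path)
}

#' Read a float/integer TIFF written by [writeImageTiff()]
#'
#' Baseline TIFF reader: uncompressed, single-sample pages, 32-bit IEEE
#' float or 8/16/32-bit unsigned integer data, either byte order. Parse
#' failures report the offending tag by name and number.
#'
#' @param path file path.
#' @return list with \code{pages} (list of matrices), \code{pixelSize}
#'   (um, from the description block if present, else from the resolution
#'   tags), \code{channels} and \code{description} (parsed YAML list or
#'   \code{NULL}).
#' @export
readImageTiff <- function(path) {
    raw <- readBin(path, "raw", file.info(path)$size)
    if (length(raw) < 8) stop("not a TIFF: file too short")
    endian <- if (rawToChar(raw[1:2]) == "II") "little"
        else if (rawToChar(raw[1:2]) == "MM") "big"
        else stop("not a TIFF: bad byte-order mark")
    rd <- function(off, size, n = 1L, what = "integer")
        readBin(raw[(off + 1):(off + size * n)], what, n = n, size = size,
                endian = endian, signed = size >= 4)
    if (rd(2, 2) != 42) stop("not a TIFF: bad magic number")
    ifdOff <- rd(4, 4)
    pages <- list(); descs <- list(); res <- NA_real_
    tagName <- function(tag) {
        nm <- .tiffTagNames[as.character(tag)]
        if (is.na(nm)) as.character(tag) else sprintf("%s (%d)", nm, tag)
    }
    while (ifdOff != 0) {
        nEntries <- rd(ifdOff, 2)
        tags <- list()
        for (e in seq_len(nEntries)) {
            eo <- ifdOff + 2 + (e - 1) * 12
            tag <- rd(eo, 2); type <- rd(eo + 2, 2); count <- rd(eo + 4, 4)
            size <- c(1, 1, 2, 4, 8)[type]
            if (is.na(size))
                stop("malformed TIFF: unsupported type ", type,
                     " in tag ", tagName(tag))
            valOff <- if (size * count <= 4) eo + 8 else rd(eo + 8, 4)
            vals <- switch(as.character(type),
                "1" = rd(valOff, 1, count),
                "2" = {
                    v <- raw[(valOff + 1):(valOff + count)]
                    rawToChar(v[cumsum(v == as.raw(0)) == 0])
                },
                "3" = rd(valOff, 2, count),
                "4" = rd(valOff, 4, count),
                "5" = {
                    v <- rd(valOff, 4, 2 * count)
                    v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
                })
            tags[[as.character(tag)]] <- vals
        }
        need <- function(tag) {
            v <- tags[[as.character(tag)]]
            if (is.null(v))
                stop("malformed TIFF: missing required tag ", tagName(tag))
            v
        }
        w <- need(256); h <- need(257)
        comp <- tags[["259"]]
        if (!is.null(comp) && comp != 1)
            stop("malformed TIFF: unsupported value in tag ",
                 tagName(259), " (only uncompressed data is supported)")
        bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
        fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
        offs <- need(273); counts <- need(279)
        data <- numeric(0)
        for (s in seq_along(offs)) {
            nval <- counts[s] / (bits / 8)
            data <- c(data, if (fmt == 3) {
                if (bits != 32)
                    stop("malformed TIFF: float data requires 32 bits in ",
                         "tag ", tagName(258))
                readBin(raw[(offs[s] + 1):(offs[s] + counts[s])],
                        "numeric", n = nval, size = 4, endian = endian)
            } else if (bits %in% c(8, 16)) {
                readBin(raw[(offs[s] + 1):(offs[s] + counts[s])],
                        "integer", n = nval, size = bits / 8,
                        endian = endian, signed = FALSE)
            } else if (bits == 32) {
                readBin(raw[(offs[s] + 1):(offs[s] + counts[s])],
                        "integer", n = nval, size = 4, endian = endian)
            } else stop("malformed TIFF: unsupported value in tag ",
                        tagName(258)))
        }
        if (length(data) != w * h)
            stop("malformed TIFF: strip sizes inconsistent with tags ",
                 tagName(256), " and ", tagName(257))
        pages[[length(pages) + 1L]] <- matrix(data, nrow = h, byrow = TRUE)
        descs[[length(pages)]] <- tags[["270"]]
        if (!is.null(tags[["282"]]) && is.na(res)) {
            unit <- if (is.null(tags[["296"]])) 2L else tags[["296"]]
            perUm <- tags[["282"]] / switch(as.character(unit),
                "2" = 2.54e4, "3" = 1e4, 1)
            res <- 1 / perUm
        }
        ifdOff <- rd(ifdOff + 2 + nEntries * 12, 4)
    }
    desc <- NULL
    for (d in descs) if (!is.null(d)) {
        desc <- tryCatch(yaml::yaml.load(d), error = function(e) NULL)
        if (!is.null(desc)) break
    }
    px <- if (!is.null(desc$pixel_size_um)) desc$pixel_size_um else res
    channels <- if (!is.null(desc$channels)) unlist(desc$channels)
        else paste0("page", seq_along(pages))
    list(pages = pages, pixelSize = px, channels = channels,
         description = desc)
}

#' Write / read a two-pass point spectrum as CSV
#'
#' Long-format CSV with columns \code{modality}, \code{wavenumber_cm1} and
#' \code{intensity}; values are written with 9 significant digits so the
#' round trip is lossless at that precision.
#'
#' @param spec a [SpectrumResult-class].
#' @param path CSV path.
#' @return \code{writeSpectrumCsv}: invisibly, the path;
#'   \code{readSpectrumCsv}: a [SpectrumResult-class].
#' @export
writeSpectrumCsv <- function(spec, path) {
    stopifnot(is(spec, "SpectrumResult"))
    df <- data.frame(
        modality = c(rep("IR", length(spec@irAxis)),
                     rep("Raman", length(spec@ramanAxis))),
        wavenumber_cm1 = sprintf("%.9g", c(spec@irAxis, spec@ramanAxis)),
        intensity = sprintf("%.9g", c(spec@irValues, spec@ramanValues)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSpectrumCsv
#' @export
readSpectrumCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("modality", "wavenumber_cm1", "intensity")
    if (!all(need %in% names(df)))
        stop("spectrum CSV needs columns: ", paste(need, collapse = ", "))
    ir <- df[df$modality == "IR", ]
    ra <- df[df$modality == "Raman", ]
    for (part in list(ir, ra))
        if (nrow(part) > 1 && any(diff(part$wavenumber_cm1) <= 0))
            stop("non-monotone wavenumber axis in spectrum CSV")
    new("SpectrumResult",
        irAxis = as.numeric(ir$wavenumber_cm1),
        irValues = as.numeric(ir$intensity),
        ramanAxis = as.numeric(ra$wavenumber_cm1),
        ramanValues = as.numeric(ra$intensity))
}

#' Export evaluated band spectra as CSV
#'
#' Wide-format CSV with columns \code{wavenumber_cm-1},
#' \code{ir_intensity} and \code{raman_intensity} for one species on a
#' common wavenumber axis.
#'
#' @param spectrum a [BandSpectrum-class].
#' @param wavenumbers strictly increasing axis (cm^-1).
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeBandSpectrumCsv <- function(spectrum, wavenumbers, path) {
    df <- data.frame(
        check.names = FALSE,
        "wavenumber_cm-1" = wavenumbers,
        ir_intensity = evaluateSpectrum(spectrum, wavenumbers, "IR"),
        raman_intensity = evaluateSpectrum(spectrum, wavenumbers, "Raman"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write / read a probe waveform
#'
#' Binary traces are single-column 32-bit float (little-endian) with a
#' YAML sidecar (\code{<path>.yaml}) holding the sample rate and the full
#' configuration provenance, so any trace can be regenerated from its
#' sidecar alone; paths ending in \code{.csv} write a one-column CSV
#' instead (for small traces).
#'
#' @param trace a [TimeTrace-class].
#' @param path output path (\code{.f32}/binary, or \code{.csv}).
#' @return \code{writeTrace}: invisibly, the path; \code{readTrace}: a
#'   [TimeTrace-class] (configuration lists from the sidecar lose their
#'   constructor classes but keep all fields).
#' @export
writeTrace <- function(trace, path) {
    stopifnot(is(trace, "TimeTrace"))
    if (grepl("\\.csv$", path)) {
        utils::write.csv(data.frame(intensity = trace@samples), path,
                         row.names = FALSE, quote = FALSE)
    } else {
        con <- file(path, "wb")
        writeBin(as.numeric(trace@samples), con, size = 4,
                 endian = "little")
        close(con)
    }
    sidecar <- c(list(sample_rate = trace@sampleRate,
                      n_samples = length(trace@samples)),
                 rapply(trace@meta, identity, how = "list"))
    yaml::write_yaml(sidecar, paste0(path, ".yaml"))
    invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
    side <- yaml::read_yaml(paste0(path, ".yaml"))
    x <- if (grepl("\\.csv$", path)) {
        utils::read.csv(path)$intensity
    } else {
        readBin(path, "numeric", n = side$n_samples, size = 4,
                endian = "little")
    }
    new("TimeTrace", samples = x, sampleRate = side$sample_rate,
        meta = side[setdiff(names(side), c("sample_rate", "n_samples"))])
}

#' Write / read a run configuration
#'
#' Run configurations are plain nested lists serialized as YAML; a run is
#' reproducible from its serialized configuration alone (all seeds
#' included). [configHash()] gives a stable digest for provenance logs.
#'
#' @param config named list.
#' @param path YAML path.
#' @return \code{readRunConfig}: the configuration list.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

#' @rdname writeRunConfig
#' @param x any R object.
#' @export
configHash <- function(x) rlang::hash(x)
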