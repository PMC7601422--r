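test_that("A1 references and column letters convert both ways", {
  expect_identical(a1_to_rc("B3"), c(3L, 2L))
  expect_identical(rc_to_a1(3L, 2L), "B3")
  expect_identical(col_letter_to_index("A"), 0L)
  expect_identical(col_letter_to_index("AB"), 27L)
  expect_identical(col_index_to_letter(27L), "AB")
  for (i in c(0L, 25L, 26L, 51L, 700L, 702L)) {
    expect_identical(col_letter_to_index(col_index_to_letter(i)), i)
  }
  expect_error(a1_to_rc("3B"), class = "fairsheet_invalid_argument")
})

test_that("workbooks survive an XLSX write/read cycle with types intact", {
  m <- matrix(list(), 3, 3)
  m[[1, 1]] <- "Namn <ö> & \"quotes\""
  m[[1, 2]] <- 3.14159
  m[[1, 3]] <- TRUE
  m[[3, 2]] <- "  spaced  "
  wb <- workbook(list(`Blad 1` = m, Tom = matrix(list(), 0, 0)))
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(wb, path)
  back <- read_workbook(path)
  expect_identical(sheet_names(back)[1], "Blad 1")
  s <- back$sheets$`Blad 1`
  expect_identical(s[[1, 1]], "Namn <ö> & \"quotes\"")
  expect_identical(s[[1, 2]], 3.14159)
  expect_identical(s[[1, 3]], TRUE)
  expect_identical(s[[3, 2]], "  spaced  ")  # trimming happens at read_cell
})

test_that("identical workbooks produce byte-identical XLSX files", {
  fx <- generate_fixture(template_spec("BLOCK_LAYOUT", seed = 12))
  p1 <- withr::local_tempfile(fileext = ".xlsx")
  p2 <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(fx$workbook, p1)
  write_workbook(fx$workbook, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("merged regions propagate the anchor value on XLSX read", {
  # build an archive with an explicit mergeCells range, as template headers do
  d <- withr::local_tempdir()
  dir.create(file.path(d, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(d, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(d, "_rels"), recursive = TRUE)
  writeLines('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>
<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">
<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>
<Default Extension="xml" ContentType="application/xml"/>
<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>
<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>
</Types>', file.path(d, "[Content_Types].xml"))
  writeLines('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>
<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">
<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>
</Relationships>', file.path(d, "_rels", ".rels"))
  writeLines('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>
<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">
<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>
</Relationships>', file.path(d, "xl", "_rels", "workbook.xml.rels"))
  writeLines('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>
<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">
<sheets><sheet name="Data" sheetId="1" r:id="rId1"/></sheets></workbook>',
    file.path(d, "xl", "workbook.xml"))
  writeLines('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>
<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">
<sheetData>
<row r="1"><c r="A1" t="inlineStr"><is><t>Group</t></is></c></row>
<row r="2"><c r="A2"><v>1</v></c><c r="B2"><v>2</v></c><c r="C2"><v>3</v></c></row>
</sheetData>
<mergeCells count="1"><mergeCell ref="A1:C1"/></mergeCells>
</worksheet>', file.path(d, "xl", "worksheets", "sheet1.xml"))
  path <- withr::local_tempfile(fileext = ".xlsx")
  zip::zip(path, c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                   "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
           root = d, mode = "mirror")
  wb <- read_workbook(path)
  s <- wb$sheets$Data
  expect_identical(s[[1, 1]], "Group")
  expect_identical(s[[1, 2]], "Group")
  expect_identical(s[[1, 3]], "Group")
})

test_that("the JSON workbook format round-trips", {
  fx <- generate_fixture(template_spec("ROW_LAYOUT", seed = 4))
  json <- workbook_to_json(fx$workbook)
  back <- workbook_from_json(json)
  expect_identical(back$sheets, fx$workbook$sheets)
  path <- withr::local_tempfile(fileext = ".json")
  write_workbook(fx$workbook, path)
  expect_identical(read_workbook(path)$sheets, fx$workbook$sheets)
})

test_that("unreadable input is an I/O error", {
  expect_error(read_workbook("no-such-file.xlsx"),
               class = "fairsheet_io_error")
  expect_error(write_workbook(workbook(list(S = matrix(list(), 1, 1))),
                              "out.unsupported"),
               class = "fairsheet_io_error")
})
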