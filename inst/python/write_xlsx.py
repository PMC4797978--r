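"""Render report tables to .xlsx with bold diagonals and band fills.

Reads a JSON job list: one entry per workbook with header, rows,
numeric column indices (1-based), bold cells, fill cells and a number
format. Written atomically (temp file + rename).
"""
import json
import os
import sys
import tempfile

from openpyxl import Workbook
from openpyxl.styles import Font, PatternFill

FILLS = {
    "green": PatternFill("solid", start_color="C6EFCE"),
    "yellow": PatternFill("solid", start_color="FFEB9C"),
    "red": PatternFill("solid", start_color="FFC7CE"),
}


def write_book(job):
    wb = Workbook()
    ws = wb.active
    ws.title = "Sheet1"
    ws.append(job["header"])
    for cell in ws[1]:
        cell.font = Font(bold=True)
    numeric = set(job.get("numeric_cols") or [])
    for row in job["rows"]:
        out = []
        for idx, value in enumerate(row, start=1):
            if idx in numeric and value is not None and value != "":
                try:
                    value = float(value)
                except (TypeError, ValueError):
                    pass
            out.append(value)
        ws.append(out)
    fmt = job.get("number_format", "0.00")
    for row in ws.iter_rows(min_row=2):
        for cell in row:
            if isinstance(cell, object) and cell.column in numeric and \
                    isinstance(cell.value, float):
                cell.number_format = fmt
    for rc in job.get("bold") or []:
        ws.cell(row=int(rc[0]), column=int(rc[1])).font = Font(bold=True)
    for fill in job.get("fills") or []:
        band = fill["band"]
        if band in FILLS:
            ws.cell(row=int(fill["row"]),
                    column=int(fill["col"])).fill = FILLS[band]
    target = job["file"]
    fd, tmp = tempfile.mkstemp(suffix=".xlsx", dir=os.path.dirname(target))
    os.close(fd)
    wb.save(tmp)
    os.replace(tmp, target)


def main():
    with open(sys.argv[1]) as fh:
        jobs = json.load(fh)
    for job in jobs:
        write_book(job)


if __name__ == "__main__":
    main()
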