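>barcode_1;size=93
TTAGGAGGCGTGTGGAGTATGTTATTAGTTAAACCATAAACGACGCCCAGTTGGATGCCATATTAGCTATAGGCTAGATTAGGTGTTCACCAGGTCATTGTTTTTTTGAGGTGTGGCGCATAAAG
>barcode_2;size=86
TTAGGAGGCGTGTGGAGTATGTTATTAGTTAAACCACAAACGACGCCCAGTTGGATGCCATATTAGCTATAGGCTAGATTAGGTGTTGACCAGGTCATTGTTTTTTTGAGGTGTGGCGCATAAAG
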