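  Assignment         w1         w2   Data Height
     G82N-H   115.3000     8.2100     1.00e+06
     A83N-H   120.1000     7.9500     9.50e+05
     I85N-H   122.4500     8.7300     1.12e+06
     Y89N-H   118.9200     9.0100     8.70e+05
     D90N-H   125.0300     8.4400     1.05e+06
        ?-?   110.0000     8.9000     2.00e+05
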