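trajectory_id,year,count
s1,2025,100
s1,2030,140
s1,2035,195
s1,2040,275
s1,2045,385
s1,2050,540
s1,2055,755
s1,2060,1055
s1,2065,1480
s1,2070,2070
s1,2075,2895
s1,2080,4055
s2,2025,90
s2,2030,130
s2,2035,180
s2,2040,250
s2,2045,350
s2,2050,490
s2,2055,685
s2,2060,960
s2,2065,1340
s2,2070,1880
s2,2075,2630
s2,2080,3680
s3,2025,110
s3,2030,155
s3,2035,215
s3,2040,300
s3,2045,420
s3,2050,590
s3,2055,825
s3,2060,1155
s3,2065,1615
s3,2070,2260
s3,2075,3165
s3,2080,4430
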