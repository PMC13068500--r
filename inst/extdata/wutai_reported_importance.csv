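response,area,predictor,ri
c,NA,NPP,53.0
c,NA,HD,17.6
c,NA,Bio1,14.5
c,NA,NDVI,7.7
z,NA,Bio14,27.5
z,NA,Bio1,22.8
z,NA,NDVI,13.7
z,NA,NPP,12.2
richness,0.0001,MDE,60.7
richness,0.0001,HD,13.2
richness,0.0001,Bio14,12.4
richness,0.0001,NPP,7.6
richness,0.01,MDE,54.8
richness,0.01,NPP,17.3
richness,0.01,Bio12,8.9
richness,0.01,Bio1,8.5
richness,0.25,MDE,61.5
richness,0.25,NPP,31.6
richness,0.25,NDVI,3.9
richness,0.25,HD,2.1
richness,1,MDE,47.4
richness,1,NPP,30.4
richness,1,HD,13.4
richness,1,NDVI,5.7
richness,25,MDE,42.8
richness,25,NPP,26.7
richness,25,HD,11.6
richness,25,NDVI,9.4
richness,100,MDE,31.4
richness,100,NPP,29.0
richness,100,HD,15.1
richness,100,Bio1,9.2
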