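sex,height_cm,L,M,S
female,45,-0.35,2.4,0.085
female,50,-0.35,3.419,0.086
female,55,-0.35,4.478,0.087
female,60,-0.35,5.579,0.088
female,65,-0.35,6.722,0.089
female,70,-0.35,7.905,0.09
female,75,-0.35,9.13,0.091
female,80,-0.35,10.395,0.092
female,85,-0.35,11.702,0.093
female,90,-0.35,13.051,0.094
female,95,-0.35,14.44,0.095
female,100,-0.35,15.871,0.096
female,105,-0.35,17.342,0.097
female,110,-0.35,18.855,0.098
female,115,-0.35,20.41,0.099
female,120,-0.35,22.005,0.1
male,45,-0.35,2.472,0.085
male,50,-0.35,3.521,0.086
male,55,-0.35,4.613,0.087
male,60,-0.35,5.747,0.088
male,65,-0.35,6.923,0.089
male,70,-0.35,8.142,0.09
male,75,-0.35,9.403,0.091
male,80,-0.35,10.707,0.092
male,85,-0.35,12.053,0.093
male,90,-0.35,13.442,0.094
male,95,-0.35,14.873,0.095
male,100,-0.35,16.347,0.096
male,105,-0.35,17.863,0.097
male,110,-0.35,19.421,0.098
male,115,-0.35,21.022,0.099
male,120,-0.35,22.665,0.1
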